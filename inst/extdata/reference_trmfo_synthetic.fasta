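>TrmFO_Tth_synthetic coordinates follow T. thermophilus TrmFO (PDB 3G5S); sequence is a synthetic stand-in
PRSIVKMTHGAGTAGLEAVMKYCDGEHPSCESQNNLRLIWARVSVKFCRCCEWWHICLHM
HVEKLLWEYRVFAQNNLKRKKSEKVRKPSVSIIDTYTQDCWKILSYYENWRHSRKENKHQ
CLQLTTDAGNDANVTRDMLYQGQWWHVWNMARIIMNEMSYDANGWIDFCHSRWYSAYFNN
GQNYPVEMIFDSSKQDPDMGIPIPKTLLFVETQMVPRLDWQACPVDKLCPFDNGGAREFK
MVGYEVQDPHFSNRFPHQASRADATQMHIQYYMMFKQSEGNLNRHCSSRYQGFNHKVNLQ
PSMEICYHRNLRERQICMGSLHWQRSVHQNMCHMTAWASQKPYMPEKSEQVYRTICSKLF
WYPLDEEEEMCLFCIDPSPSVHAKGDASSQYPSHDCKFSRRAISGTESYYHFGMHPLKAF
NAFLACMSEHTVQIVWTTWQAMWHY
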