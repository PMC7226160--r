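species	group	mycoides_cluster
Acholeplasma_laidlawii	AAP	FALSE
Candidatus_Phytoplasma_asteris	AAP	FALSE
Candidatus_Phytoplasma_australiense	AAP	FALSE
Candidatus_Phytoplasma_mali	AAP	FALSE
Spiroplasma_citri	S	FALSE
Spiroplasma_melliferum	S	FALSE
Spiroplasma_chrysopicola	S	FALSE
Spiroplasma_apis	S	FALSE
Mesoplasma_florum	S	FALSE
Mycoplasma_auris	S	FALSE
Mycoplasma_yeatsii	S	FALSE
Mycoplasma_putrefaciens	S	FALSE
Mycoplasma_mycoides_subsp_mycoides	S	TRUE
Mycoplasma_mycoides_subsp_capri	S	TRUE
Mycoplasma_capricolum_subsp_capricolum	S	TRUE
Mycoplasma_capricolum_subsp_capripneumoniae	S	TRUE
Mycoplasma_agalactiae	H	FALSE
Mycoplasma_bovis	H	FALSE
Mycoplasma_bovigenitalium_cl-51080	H	FALSE
Mycoplasma_fermentans	H	FALSE
Mycoplasma_hominis	H	FALSE
Mycoplasma_arthritidis	H	FALSE
Mycoplasma_pulmonis	H	FALSE
Mycoplasma_mobile	H	FALSE
Mycoplasma_crocodyli	H	FALSE
Mycoplasma_synoviae	H	FALSE
Mycoplasma_conjunctivae	H	FALSE
Mycoplasma_hyorhinis	H	FALSE
Mycoplasma_hyopneumoniae	H	FALSE
Mycoplasma_flocculare	H	FALSE
Mycoplasma_ovipneumoniae	H	FALSE
Mycoplasma_pneumoniae	P	FALSE
Mycoplasma_genitalium	P	FALSE
Mycoplasma_gallisepticum	P	FALSE
Mycoplasma_imitans	P	FALSE
Mycoplasma_penetrans	P	FALSE
Mycoplasma_iowae	P	FALSE
Ureaplasma_parvum	P	FALSE
Ureaplasma_urealyticum	P	FALSE
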