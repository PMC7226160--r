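((Acholeplasma_laidlawii:0.22,(Candidatus_Phytoplasma_asteris:0.12,(Candidatus_Phytoplasma_australiense:0.08,Candidatus_Phytoplasma_mali:0.09)n40:0.05)2:0.10)3:0.08,(((Spiroplasma_citri:0.09,(Spiroplasma_melliferum:0.07,(Spiroplasma_chrysopicola:0.06,Spiroplasma_apis:0.08)n43:0.04)n42:0.04)n41:0.06,(Mesoplasma_florum:0.14,(Mycoplasma_auris:0.09,((Mycoplasma_yeatsii:0.05,Mycoplasma_putrefaciens:0.06)n47:0.04,((Mycoplasma_mycoides_subsp_mycoides:0.03,Mycoplasma_mycoides_subsp_capri:0.03)n48:0.02,(Mycoplasma_capricolum_subsp_capricolum:0.02,Mycoplasma_capricolum_subsp_capripneumoniae:0.02)n49:0.02)33:0.03)n46:0.03)34:0.05)n44:0.05)36:0.05,((((Mycoplasma_agalactiae:0.04,Mycoplasma_bovis:0.04)n51:0.08,(Mycoplasma_bovigenitalium_cl-51080:0.10,Mycoplasma_fermentans:0.12)n52:0.03)n50:0.04,(((Mycoplasma_hominis:0.10,Mycoplasma_arthritidis:0.11)n54:0.04,(Mycoplasma_pulmonis:0.13,Mycoplasma_mobile:0.12)n55:0.05)n53:0.03,(Mycoplasma_crocodyli:0.12,((Mycoplasma_synoviae:0.09,Mycoplasma_conjunctivae:0.10)n58:0.03,(Mycoplasma_hyorhinis:0.11,(Mycoplasma_hyopneumoniae:0.05,(Mycoplasma_flocculare:0.04,Mycoplasma_ovipneumoniae:0.05)n60:0.02)19:0.04)n59:0.03)n57:0.03)n56:0.03)n61:0.03)27:0.06,(((Mycoplasma_pneumoniae:0.08,Mycoplasma_genitalium:0.09)n63:0.05,(Mycoplasma_gallisepticum:0.10,Mycoplasma_imitans:0.09)n64:0.04)n62:0.05,((Mycoplasma_penetrans:0.11,Mycoplasma_iowae:0.10)n66:0.04,(Ureaplasma_parvum:0.05,Ureaplasma_urealyticum:0.05)n67:0.08)n65:0.06)12:0.08)28:0.05)37:0.06)38;
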