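name	start	end
pre_helixA	313	321
helixA	322	357
helixA_B_linker	358	534
helixB	535	557
helixB_C_linker	558	588
helixC	589	620
helixC_D_linker	621	638
helixD	639	672
distal_cterm	673	872
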