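name	start	end
S1	92	112
S2	123	143
S3	167	187
S4	196	218
S5	232	252
pore_loop	260	291
S6	292	312
pre_helixA	313	321
helixA	322	357
helixA_B_linker	358	534
helixB	535	557
helixB_C_linker	558	588
helixC	589	620
helixD	639	672
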