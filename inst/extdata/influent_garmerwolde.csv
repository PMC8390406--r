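date,weather,tcod,scod,bod5,tss,vss,protein_sol,protein_tot,carb_sol,carb_tot,humic_sol,humic_tot,lipid,vfa
2019-05-01,DWF,567,143,129,393,220,13,66,13,110,99,157,22,58
2019-05-07,DWF,703,133,238,445,308,18,86,9,210,65,101,,9
2019-05-08,DWF,587,127,283,384,172,21,52,8,109,67,148,,40
2020-02-26,WWF,301,,,,,,,,,,,17,
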