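# synthetic DSC-style example generated by generate_tg(tg_scenario(seed = 7))
xw,tg_c
0.0200000000000000,4.76140082037154
0.0511111111111111,-0.21389126619805
0.0822222222222222,-1.26847938280441
0.1133333333333333,-2.61379356436817
0.1444444444444444,-4.87459756304100
0.1755555555555555,-6.63406061362411
0.2066666666666666,-6.80776873059082
0.2377777777777777,-9.63467878593050
0.2688888888888888,-11.42663925930581
0.3000000000000000,-11.55845743710116
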