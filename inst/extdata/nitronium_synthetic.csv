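# SYNTHETIC nitronium-fraction table generated by nitrokinetics::generate_nitronium_table()
# from the package default ground truth (noise-free). It is a stand-in for literature
# lg(c_NO2+/c_HNO3) measurements, which this package does not ship; do not treat as data.
temperature_C,w_h2so4_percent,lg_ratio
23,88,-1.144833
23,90,-0.581766
23,92,-0.018699
23,94,0.544367
23,96,1.107434
23,98,1.670501
40,88,-1.355639
40,90,-0.799904
40,92,-0.24417
40,94,0.311564
40,96,0.867299
40,98,1.423033
60,88,-1.576101
60,90,-1.028035
60,92,-0.479969
60,94,0.068097
60,96,0.616163
60,98,1.164229
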