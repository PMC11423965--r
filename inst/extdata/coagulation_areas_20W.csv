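gold_mm2,hyperechoic_mm2,ml_mm2,er_hyperechoic_printed,er_ml_printed
193.357,236.522,188.719,0.223,0.024
261.281,308.494,205.808,0.181,0.212
256.924,301.556,207.278,0.174,0.193
241.527,281.911,217.388,0.167,0.100
264.442,307.946,242.652,0.165,0.082
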