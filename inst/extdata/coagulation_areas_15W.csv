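gold_mm2,hyperechoic_mm2,ml_mm2,er_hyperechoic_printed,er_ml_printed
192.969,258.423,133.690,0.339,0.307
153.100,221.558,146.042,0.447,0.046
176.083,233.870,144.782,0.328,0.178
152.061,218.191,178.112,0.435,0.171
169.047,246.556,153.136,0.459,0.094
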