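variant,map_50,map_75
high quality dataset,0.314,0.255
low quality dataset,0.226,0.156
"subsampling x2, SR x2",0.198,0.120
"SR x2, subsampling x2",0.233,0.110
"subsampling x4, SR x4",0.227,0.155
"SR x4, subsampling x4",0.279,0.195
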