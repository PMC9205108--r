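"dimension","L1","L2","L3","L4","L5"
"pain",0,0,0.077,0.187,0.384
"fatigue",0,0.054,0.075,0.144,0.164
"nausea",0,0.099,0.149,0.162,0.298
"sleep",0,0,0,0.077,0.077
"work",0,0.057,0.09,0.09,0.231
"support",0,0.022,0.022,0.12,0.195
"sadness",0,0,0.127,0.127,0.185
"worry",0,0.097,0.097,0.097,0.118
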