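participant_id,condition_id,x,y
P01,L1,0.05,0.12
P01,L1,4.21,1.73
P01,L1,-4.33,10.18
P02,L1,5.94,6.82
P02,L1,-5.87,4.91
P02,L1,0.31,12.04
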