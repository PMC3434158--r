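# 4-year counts of grouped individuals at 16 sites (worked example)
time,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16
1,1,0,0,0,1,2,1,2,0,0,0,3,1,2,0,3
2,0,2,0,0,2,1,0,0,2,3,0,2,3,0,2,3
3,0,0,3,0,0,0,3,0,1,0,2,1,0,3,2,3
4,0,0,0,1,0,0,0,2,0,1,3,0,2,2,2,3
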