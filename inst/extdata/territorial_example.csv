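# 4-year presence/absence survey of 16 territories (worked example)
time,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16
1,1,0,0,0,1,1,1,1,0,0,0,1,1,1,0,1
2,0,1,0,0,1,1,0,0,1,1,0,1,1,0,1,1
3,0,0,1,0,0,0,1,0,1,0,1,1,0,1,1,1
4,0,0,0,1,0,0,0,1,0,1,1,0,1,1,1,1
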