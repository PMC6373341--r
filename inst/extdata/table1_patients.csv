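age,sex,site,chemo,stage,restaging,watch_and_wait,note
49,1,2,2,cT3 cN2 cM0,ycT0 ycN0 ycM0,1,
80,1,1,1,cT4 cN2 cM0,ycT2/3 ycN1 ycM0,0,
65,2,3,2,cT4 cN2 cM0,ycT0 ycN0 ycM0,1,
75,1,2,1,cT4a cN1 cM0,ycT2 ycN0 ycM0,0,
56,1,2,2,cT3 cN2 cM0,ycT2/3 ycN1 ycM0,0,
77,1,3,1,cT4 cN0 cM0,ycT0 ycN0 ycM0,1,
86,1,1,0,cT3 cN1 cM0,ycT0 ycN0 ycM0,1,
61,2,2,1,cT3 cN0 cM0,ycT3 ycN0 ycM0,0,
71,1,2,2,cT4a cN2 cM0,ycT0 ycN0 ycM0,1,column-run ambiguity in source layout; parsed by column domains
62,1,2,2,cT3 cN2 cM0,ycT3 ycN1 ycM0,0,
54,1,3,2,cT3 cN1 cM0,ycT2 ycN0 ycM0,0,
69,1,2,1,cT3 cN1 cM0,ycT3 ycN0 ycM0,0,
60,2,2,2,cT4 cN2 cM0,ycT4 ycN0 ycM0,0,
55,1,2,2,cT3 cN1 cM0,ycT3 ycN0 ycM0,0,
52,1,2,1,cT2 cN1 cM0,ycT2 ycN0 ycM0,0,
54,1,2,2,cT3 cN1 cM0,ycT3 ycN0 ycM0,0,
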