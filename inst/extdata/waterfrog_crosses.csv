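cross_id,father_id,gamete_classes,rr_male,rr_female,rr_undetermined,rl_male,rl_female,rl_undetermined
25-2013,M1,[L],0,0,0,20,0,0
32-2013,M1,[L],0,0,0,3,0,0
65-2013,M3,[L],0,0,0,1,0,0
49-2013,M4,[L]/[R],0,1,0,1,0,0
39-2013,M4,[R],0,22,0,0,0,0
42-2013,M5,[L],0,0,0,64,0,0
53-2013,M8,[L],0,0,0,2,0,0
41-2013,M9,[L],0,0,0,20,0,0
57-2013,M10,[L],0,0,0,3,0,0
66-2013,M10,[L],0,0,0,20,0,2
27-2013,M11,[L]/[R],0,14,1,11,0,0
30-2013,M11,[L]/[R],0,28,0,21,0,0
59-2013,M12,[R],0,2,1,0,0,0
60-2013,M13,[L],0,0,0,19,0,0
54-2013,M14,[L],0,0,0,2,0,0
63-2013,M14,[L],0,0,0,3,0,0
26-2013,M16,[L],0,0,0,17,0,0
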