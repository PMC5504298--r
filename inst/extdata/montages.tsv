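config_id	name	channels
1	motor+premotor	FC5,FC1,FC2,FC6,C3,C1,CZ,C2,C4
2	motor	C3,C1,CZ,C2,C4
3	premotor	FC5,FC1,FC2,FC6
4	left motor+premotor	FC5,FC1,C3,C1
5	left motor+premotor+medial	FC5,FC1,C3,C1,CZ,CP1
6	right motor+premotor	FC2,FC6,C2,C4
7	right motor+premotor+medial	FC2,FC6,C2,C4,CZ,CP2
8	reduced motor+premotor	FC1,FC2,C3,CZ,C4
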