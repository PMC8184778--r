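case_no,shape,sex,age,symptoms,mexiletine,heart_rate_bpm
1,Asymmetric,M,13,Syncope,On,53
2,Asymmetric,M,11,None,Off,76
3,Asymmetric,F,6,Convulsions,On,80
4,Late-onset,M,13,Syncope,On,66
5,Late-onset,F,15,None,On,48
6,Late-onset,F,12,Syncope,On,60
7,Late-onset,M,9,None,On,83
8,Late-onset,F,22,None,Off,59
9,Late-onset,F,59,None,Off,54
10,Late-onset,M,10,None,Off,62
11,Late-onset,M,19,None,Off,51
12,Late-onset,M,17,None,Off,47
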