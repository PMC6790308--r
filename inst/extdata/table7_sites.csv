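patient,site_description,region,hemisphere,rest_only
3,Left MTG,MTG,L,TRUE
4,Left ANG,ANG,L,FALSE
4,Left MTG,MTG,L,TRUE
5,Left IFG,IFG,L,FALSE
6,Left IFG,IFG,L,FALSE
7,Left IFG,IFG,L,TRUE
8,Left IFG,IFG,L,FALSE
11,Left MFG,MFG,L,FALSE
12,Left IFG,IFG,L,FALSE
13,Left IFG,IFG,L,FALSE
15,Left IFG,IFG,L,TRUE
16,Left IFG,IFG,L,TRUE
17,Left IFG,IFG,L,FALSE
18,Left ANG,ANG,L,FALSE
19,Left IFG,IFG,L,FALSE
20,Left IFG,IFG,L,FALSE
21,Left ANG,ANG,L,FALSE
22,Left MTG,MTG,L,FALSE
25,Right IFG,IFG,R,TRUE
27,Left SMA/pre-SMA,SMA_preSMA,L,FALSE
28,Left superior frontal gyrus,SFG,L,TRUE
30,Left IFG,IFG,L,TRUE
31,Left MTG,MTG,L,FALSE
32,Left MTG,MTG,L,TRUE
36,Left ANG,ANG,L,FALSE
37,Left MTG,MTG,L,FALSE
40,Left IFG,IFG,L,FALSE
42,Left superior frontal junction,SFJ,L,TRUE
44,Left middle temporal gyrus,MTG,L,FALSE
45,Posterior part of left middle frontal gyrus,MFG,L,FALSE
46,Left middle temporal gyrus,MTG,L,TRUE
48,Middle part of left inferior frontal gyrus,IFG,L,FALSE
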