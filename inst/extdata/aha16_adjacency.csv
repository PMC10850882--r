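from,to
1,2
2,3
3,4
4,5
5,6
6,1
7,8
8,9
9,10
10,11
11,12
12,7
13,14
14,15
15,16
16,13
1,7
2,8
3,9
4,10
5,11
6,12
7,13
8,13
12,13
8,14
9,14
9,15
10,15
11,15
11,16
12,16
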