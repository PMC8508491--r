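index,residue_type,x,y,z
1,R,36.592,37.483,11.446
2,R,33.218,25.67,20.764
3,R,29.464,5.387,26.28
4,R,28.203,18.31,28.764
5,K,37.387,10.217,18.492
6,K,37.601,39.129,4.699
7,K,19,22.413,36.161
8,K,5.548,39.556,37.867
9,K,3.298,20.568,15.608
10,K,36.23,17.879,33.44
11,K,29.504,32.442,15.524
12,K,27.407,0.158,33.317
13,K,0.293,8.306,36.264
14,K,24.471,15.182,17.431
15,H,1.497,38.942,17.27
16,H,38.303,35.51,25.599
17,H,38.839,24.754,13.337
18,H,13.87,15.939,31.388
19,N-terminus,1.557,29.952,27.091
20,N-terminus,6.851,10.444,20.577
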