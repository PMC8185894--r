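chromosome,size_mb,proliferating,quiescent,senescent,provenance
1,249.25,intermediate,peripheral,peripheral,stated
2,243.20,peripheral,peripheral,peripheral,stated
3,198.02,peripheral,peripheral,peripheral,stated
4,191.15,peripheral,peripheral,peripheral,stated
5,180.92,intermediate,intermediate,peripheral,stated
6,171.12,intermediate,peripheral,peripheral,inferred
7,159.14,peripheral,peripheral,peripheral,stated
X,155.27,peripheral,peripheral,peripheral,stated
8,146.36,intermediate,peripheral,intermediate,inferred
9,141.21,peripheral,peripheral,peripheral,stated
10,135.53,intermediate,peripheral,interior,stated
11,135.01,intermediate,interior,intermediate,inferred
12,133.85,peripheral,interior,interior,inferred
13,115.17,peripheral,interior,interior,stated
14,107.35,interior,interior,interior,stated
15,102.53,peripheral,intermediate,interior,inferred
16,90.35,interior,interior,intermediate,inferred
17,81.20,interior,interior,interior,stated
18,78.08,peripheral,interior,interior,stated
20,63.03,interior,intermediate,interior,inferred
Y,59.37,interior,interior,interior,stated
19,59.13,interior,interior,interior,stated
22,51.30,interior,interior,interior,stated
21,48.13,interior,interior,interior,stated
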