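ID nfkb_p50_synthetic
BF NF-kB p50 homodimer
P0      A      C      G      T
01      1      0     16      1      G
02      0      0     18      0      G
03      0      1     17      0      G
04      6      0     12      0      R
05     14      1      2      1      A
06      2      4      2     10      T
07      0      6      0     12      Y
08      0     15      0      3      C
09      0     17      1      0      C
10      1     16      0      1      C
//
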