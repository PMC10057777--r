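
Last position-specific scoring matrix computed
              A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 P   -3   1   2   2   2  -3  -3  -4   0  -2  -3  -1   1  -1   7  -1  -4   1   2   1
    2 L   -3  -1   1   0   1  -1  -2  -1  -1  -4   8   1   0  -2  -2  -2  -4   0   1  -4
    3 M   -4   0   0  -3   1   0  -3   2  -3   1  -4   1   8   1  -2   0  -3   2   0  -2
    4 L   -4   1  -2  -4  -2  -3  -4  -1   0  -1   7   0  -4   2   2   1  -1   0   2  -3
    5 L    0   1   0   2  -2  -2  -1   0  -1   1   8   1  -2  -2  -1  -1  -2  -4  -4  -3
    6 K   -1   1  -2   2  -2  -3   2  -4   1   0  -2   7   2  -2  -2  -4  -2  -4  -3  -2

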