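
Last position-specific scoring matrix computed
              A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  V  Y  A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  V  Y
    1 A   7 -3 -1 -2 -3 -2 -2 -1 -3 -3 -2  0  0 -2 -1  0 -3 -3 -3 -2   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5  1.00 0.50
    2 S   0 -2 -1 -1 -3 -2 -1 -3 -3 -3 -2 -1 -1 -2  0  6 -1  0 -1 -2   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5  1.00 0.50
    3 D  -1 -3 -2  6 -3 -2 -3 -3 -2 -2 -3 -3 -2 -2  0  0 -2  0  0 -1   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5  1.00 0.50
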