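8
b1             0          1.37          1.44          1.51          1.58          1.65          1.72          1.79
b2          1.37             0          1.37          1.44          1.51          1.58          1.65          1.72
b3          1.44          1.37             0          1.37          1.44          1.51           0.2           0.3
b4          1.51          1.44          1.37             0          1.37          1.44          1.51          1.58
b5          1.58          1.51          1.44          1.37             0          1.37          1.44          1.51
b6          1.65          1.58          1.51          1.44          1.37             0          1.37          1.44
b7          1.72          1.65           0.2          1.51          1.44          1.37             0           0.4
b8          1.79          1.72           0.3          1.58          1.51          1.44           0.4             0
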