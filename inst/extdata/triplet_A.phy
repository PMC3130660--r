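5
a1             0          0.97          1.04          1.11          1.18
a2          0.97             0           0.4          1.04           0.6
a3          1.04           0.4             0          0.97           0.8
a4          1.11          1.04          0.97             0          0.97
a5          1.18           0.6           0.8          0.97             0
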