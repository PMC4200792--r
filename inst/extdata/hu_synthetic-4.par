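   14 # base-pair steps
#    Shift      Slide       Rise       Tilt       Roll      Twist
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000    90.0000    28.0000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000    90.0000    28.0000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
    0.0000     0.0000     3.4000     0.0000     4.0000    33.5000
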