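# Two-genome worked example over universe {a, b, c, d}:
# A = linear a b -d (marker c absent), B = linear b c d (marker a absent).
# Rank distance d_r(A, B) = 8.
>A
a b -d $
>B
b c d $
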