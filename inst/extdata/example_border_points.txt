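# Example lesion-border control points (synthetic, hand-placed), row col,
# 1-based, for a 200 x 200 image. Trace an irregular closed lesion outline.
60 95
68 130
88 150
112 155
135 142
148 118
150 92
140 68
118 52
95 48
72 55
58 72
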