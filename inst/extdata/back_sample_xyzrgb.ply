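ply
format ascii 1.0
comment eight published sample vertices of a sow back capture (with RGB)
element vertex 8
property float x
property float y
property float z
property uchar red
property uchar green
property uchar blue
end_header
-0.26387 0.02476 -1.68700 137 128 119
-0.25939 0.02476 -1.68700 137 130 120
-0.25431 0.02470 -1.68300 136 127 122
-0.24984 0.02470 -1.68300 134 119 118
-0.24537 0.02470 -1.68300 125 110 109
-0.24148 0.02476 -1.68700 123 108 107
-0.23770 0.02483 -1.69200 125 111 105
-0.23321 0.02483 -1.69200 128 109 103
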