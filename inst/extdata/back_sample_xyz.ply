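ply
format ascii 1.0
comment eight published sample vertices of a sow back capture (coordinates only)
element vertex 8
property float x
property float y
property float z
end_header
-0.26387 0.02476 -1.68700
-0.25939 0.02476 -1.68700
-0.25431 0.02470 -1.68300
-0.24984 0.02470 -1.68300
-0.24537 0.02470 -1.68300
-0.24148 0.02476 -1.68700
-0.23770 0.02483 -1.69200
-0.23321 0.02483 -1.69200
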