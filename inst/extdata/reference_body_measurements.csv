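id,true_shoulder,extracted_shoulder,true_abdomen,extracted_abdomen,true_hip,extracted_hip
1,0.395,0.386,0.481,0.492,0.404,0.414
2,0.433,0.451,0.368,0.357,0.378,0.365
3,0.291,0.285,0.324,0.304,0.321,0.306
4,0.411,0.396,0.316,0.325,0.422,0.434
5,0.491,0.474,0.395,0.417,0.335,0.323
6,0.415,0.425,0.361,0.373,0.381,0.362
7,0.401,0.385,0.362,0.350,0.401,0.420
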