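Subset,S_WAG,S_LG,Q,TreeHeight,Shape,A,B,C,CP1,NUMB
Full,0.9,0.86,48.8,3.69,1.17,4,3,1,2,103
urzyme,0.87,0.82,52.4,3.40,1.60,4,3,1,0,83
Protoz,0.85,0.85,52.3,2.71,1.38,4,0,0,0,46
CP1,0.34,0.35,33.7,2.17,4.49,0,0,0,2,20
Urz_0,0.76,0.73,50.1,3.03,1.46,1,1,0,0,20
Urz_1,0.71,0.68,57.8,3.99,0.91,0,1,0.5,0,20
Urz_2,0.72,0.7,55,2.78,1.13,2,0,0,0,20
Urz_3,0.62,0.62,45.6,2.54,2.26,0,2,0,0,20
Urz_4,0.82,0.77,58.5,2.41,1.21,2,1,0.5,0,20
Urz_5,0.78,0.8,45.6,2.88,1.98,4,0,0,0,20
Urz_6,0.62,,56.6,2.65,1.13,0,2,1,0,20
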