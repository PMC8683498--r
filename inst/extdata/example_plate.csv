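,0,3.7037037037037,11.1111111111111,33.3333333333333,100,300
0,1,0.978056297000211,0.97671052589655,0.883575576098038,0.737603485042106,0.472826408969419
1.23456790123457,0.984132011564339,0.860991982994382,0.896820130147731,0.777146363819552,0.641976233327165,0.39595819357125
3.7037037037037,0.980998286533915,0.841010505371111,0.807348320412648,0.749477595424978,0.626330195848392,0.37438942491167
11.1111111111111,0.868094383957244,0.79513215798703,0.768755815037447,0.694357273985379,0.604415047677985,0.351076100811658
33.3333333333333,0.743409844563693,0.610618035167568,0.623538090976265,0.573508700332696,0.472063001102172,0.302541191136572
100,0.51640936768236,0.386105574296162,0.363266132929151,0.389787033917268,0.266641168796006,0.158299891265994
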