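# Pure-water Napierian absorption coefficients a_w (1/m), 300-720 nm.
# SYNTHETIC smooth compilation approximating published pure-water values
# (visible band close to the Pope & Fry 1997 integrating-cavity data; UV
# tail a smooth monotone extension). Bundled as the default a_w table for
# absorption-budget partitioning; replaceable by the user.
wavelength_nm,a_w_m1
300,0.045
310,0.035
320,0.028
330,0.022
340,0.018
350,0.015
360,0.013
370,0.011
380,0.01
390,0.0085
400,0.0066
410,0.0047
420,0.0045
430,0.005
440,0.0064
450,0.0092
460,0.0098
470,0.0106
480,0.0127
490,0.015
500,0.0204
510,0.0325
520,0.0409
530,0.0434
540,0.0474
550,0.0565
560,0.0619
570,0.0695
580,0.0896
590,0.1351
600,0.2224
610,0.2644
620,0.2755
630,0.2916
640,0.3108
650,0.34
660,0.41
670,0.439
680,0.465
690,0.516
700,0.624
710,0.827
720,1.231
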