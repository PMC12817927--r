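medium	mw	d_cm2_s
lumen	1.80e+01	4.71404520791032e-09
lumen	6.00e+01	2.58198889747161e-09
lumen	1.80e+02	1.49071198499986e-09
lumen	3.42e+02	1.08147614087175e-09
lumen	1.00e+03	6.32455532033676e-10
mucus	1.80e+01	2.35702260395516e-09
mucus	6.00e+01	1.29099444873581e-09
mucus	1.80e+02	7.45355992499930e-10
mucus	3.42e+02	5.40738070435875e-10
mucus	1.00e+03	3.16227766016838e-10
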