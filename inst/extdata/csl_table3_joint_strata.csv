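voc,window,level,enclave,n_gdm,n_no_gdm
benzene,preconception,low,yes,13,229
benzene,preconception,low,no,415,3700
benzene,preconception,high,yes,129,1520
benzene,preconception,high,no,342,2721
benzene,first_trimester,low,yes,15,230
benzene,first_trimester,low,no,420,3759
benzene,first_trimester,high,yes,127,1519
benzene,first_trimester,high,no,337,2662
ethylbenzene,preconception,low,yes,15,230
ethylbenzene,preconception,low,no,406,3510
ethylbenzene,preconception,high,yes,127,1519
ethylbenzene,preconception,high,no,351,2911
ethylbenzene,first_trimester,low,yes,15,230
ethylbenzene,first_trimester,low,no,412,3531
ethylbenzene,first_trimester,high,yes,127,1519
ethylbenzene,first_trimester,high,no,345,2890
mtbe,preconception,low,yes,63,675
mtbe,preconception,low,no,437,4141
mtbe,preconception,high,yes,79,1074
mtbe,preconception,high,no,320,2280
mtbe,first_trimester,low,yes,50,546
mtbe,first_trimester,low,no,419,4017
mtbe,first_trimester,high,yes,92,1203
mtbe,first_trimester,high,no,338,2404
n_hexane,preconception,low,yes,44,491
n_hexane,preconception,low,no,373,3461
n_hexane,preconception,high,yes,98,1258
n_hexane,preconception,high,no,384,2960
n_hexane,first_trimester,low,yes,32,378
n_hexane,first_trimester,low,no,388,3596
n_hexane,first_trimester,high,yes,110,1371
n_hexane,first_trimester,high,no,369,2825
emk,preconception,low,yes,58,681
emk,preconception,low,no,490,4337
emk,preconception,high,yes,84,1068
emk,preconception,high,no,267,2084
emk,first_trimester,low,yes,54,573
emk,first_trimester,low,no,460,4155
emk,first_trimester,high,yes,88,1176
emk,first_trimester,high,no,297,2266
m_xylene,preconception,low,yes,15,230
m_xylene,preconception,low,no,408,3501
m_xylene,preconception,high,yes,127,1519
m_xylene,preconception,high,no,349,2920
m_xylene,first_trimester,low,yes,15,230
m_xylene,first_trimester,low,no,410,3516
m_xylene,first_trimester,high,yes,127,1519
m_xylene,first_trimester,high,no,347,2905
o_xylene,preconception,low,yes,18,286
o_xylene,preconception,low,no,405,3492
o_xylene,preconception,high,yes,124,1463
o_xylene,preconception,high,no,352,2929
o_xylene,first_trimester,low,yes,15,231
o_xylene,first_trimester,low,no,410,3526
o_xylene,first_trimester,high,yes,127,1518
o_xylene,first_trimester,high,no,347,2895
p_xylene,preconception,low,yes,31,407
p_xylene,preconception,low,no,399,3469
p_xylene,preconception,high,yes,111,1342
p_xylene,preconception,high,no,358,2952
p_xylene,first_trimester,low,yes,24,314
p_xylene,first_trimester,low,no,406,3494
p_xylene,first_trimester,high,yes,118,1435
p_xylene,first_trimester,high,no,351,2927
propene,preconception,low,yes,67,760
propene,preconception,low,no,449,4279
propene,preconception,high,yes,75,989
propene,preconception,high,no,308,2142
propene,first_trimester,low,yes,74,871
propene,first_trimester,low,no,420,4051
propene,first_trimester,high,yes,68,878
propene,first_trimester,high,no,337,2370
sesquiterpene,preconception,low,yes,62,756
sesquiterpene,preconception,low,no,355,3398
sesquiterpene,preconception,high,yes,80,993
sesquiterpene,preconception,high,no,402,3023
sesquiterpene,first_trimester,low,yes,62,679
sesquiterpene,first_trimester,low,no,360,3481
sesquiterpene,first_trimester,high,yes,80,1070
sesquiterpene,first_trimester,high,no,397,2940
toluene,preconception,low,yes,19,315
toluene,preconception,low,no,407,3484
toluene,preconception,high,yes,123,1434
toluene,preconception,high,no,350,2937
toluene,first_trimester,low,yes,15,230
toluene,first_trimester,low,no,411,3523
toluene,first_trimester,high,yes,127,1519
toluene,first_trimester,high,no,346,2898
styrene,preconception,low,yes,64,672
styrene,preconception,low,no,657,5611
styrene,preconception,high,yes,78,1077
styrene,preconception,high,no,100,810
styrene,first_trimester,low,yes,52,567
styrene,first_trimester,low,no,661,5605
styrene,first_trimester,high,yes,90,1182
styrene,first_trimester,high,no,96,816
butadiene_13,preconception,low,yes,64,668
butadiene_13,preconception,low,no,642,5555
butadiene_13,preconception,high,yes,78,1081
butadiene_13,preconception,high,no,115,866
butadiene_13,first_trimester,low,yes,51,544
butadiene_13,first_trimester,low,no,673,5681
butadiene_13,first_trimester,high,yes,91,1205
butadiene_13,first_trimester,high,no,84,740
cyclohexane,preconception,low,yes,66,956
cyclohexane,preconception,low,no,391,3356
cyclohexane,preconception,high,yes,76,793
cyclohexane,preconception,high,no,366,3065
cyclohexane,first_trimester,low,yes,74,942
cyclohexane,first_trimester,low,no,400,3394
cyclohexane,first_trimester,high,yes,68,807
cyclohexane,first_trimester,high,no,357,3027
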