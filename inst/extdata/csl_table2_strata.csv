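characteristic,stratum,n_gdm,n_no_gdm
enclave,yes,142,1749
enclave,no,757,6421
age,under_20,4,164
age,20_24,74,1215
age,25_29,226,2571
age,30_34,318,2640
age,35_plus,277,1574
age,missing,0,6
bmi,obese,75,350
bmi,overweight,111,633
bmi,normal,282,3184
bmi,underweight,31,590
bmi,unknown,400,3413
insurance,private,677,5697
insurance,public,124,1156
insurance,self_pay,18,175
insurance,other,80,1142
marital,married,800,6842
marital,single,78,1163
marital,divorced,21,165
parity,nulliparous,395,4038
parity,multiparous,504,4132
hospital,university,329,3387
hospital,community_teaching,541,4407
hospital,community_nonteaching,29,376
season,spring,203,1937
season,summer,208,2155
season,fall,250,2187
season,winter,238,1891
poverty,high,348,2975
poverty,low,551,5195
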