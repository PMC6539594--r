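id,subseries,sequence,rt_min,formula_printed,calc_mz_printed,meas_mz_printed,charge,inh,inh_sd,logIC50,logIC50_se,dr_r2,ic50_uM_printed
1,linker,Lys(Har)-GlyΨ[Trl]Arg,11.98,C22H43N13O4,554.3634,554.3640,1,28.1,1.2,,,,
2,linker,D-Lys(Har)-GlyΨ[Trl]Arg,11.96,C22H43N13O4,554.3634,554.3656,1,33.1,1.9,,,,
3,linker,Lys(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg,13.22,C25H46N16O4,635.3961,635.3979,1,58.1,2.1,-5.076,0.06,0.9859,8.39
4,linker,D-Lys(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg,13.30,C25H46N16O4,635.3961,635.3980,1,52.6,1.3,-4.991,0.05,0.9921,10.22
5,linker,D-Lys(D-Har)-GlyΨ[Trl]GlyΨ[Trl]Arg,13.33,C25H46N16O4,635.3961,635.3982,1,48.5,2.9,-5.040,0.1417,0.9358,9.11
6,linker,Lys(Har)-Pro-GlyΨ[Trl]Arg,14.65,C27H50N14O5,651.4161,651.4187,1,18.3,0.9,,,,
7,linker,D-Lys(Har)-Pro-GlyΨ[Trl]Arg,14.65,C27H50N14O5,651.4161,651.4190,1,38.4,1.5,,,,
8,linker,Lys(Har)-Phe-GlyΨ[Trl]Arg,14.89,C31H52N14O5,701.4318,701.4339,1,30.9,2.1,,,,
9,linker,D-Lys(Har)-Phe-GlyΨ[Trl]Arg,15.04,C31H52N14O5,701.4318,701.4338,1,37.9,1.1,,,,
10,linker,Lys(Har)-GlyΨ[Trl]Ala-Arg,13.17,C25H48N14O5,625.4005,625.3994,1,43.2,1.5,,,,
11,linker,Lys(Har)-GlyΨ[Trl]Gly-Arg,12.19,C24H46N14O5,611.3848,611.3878,1,30.6,1.1,,,,
12,linker,Har-Pro-GlyΨ[Trl]Arg,13.78,C21H38N12O4,523.3212,523.3221,1,9.2,0.8,,,,
13,linker,Har-GlyΨ[Trl]GlyΨ[Trl]GlyΨ[Trl]Arg,14.52,C22H37N17O3,588.3338,588.3362,1,34.8,1.5,,,,
14,arm,Lys(Fmoc-Har)-GlyΨ[Trl]GlyΨ[Trl]Arg,16.50,C40H56N16O6,429.2357,429.2371,2,57.7,1.8,,,,
15,arm,D-Lys(Fmoc-Har)-GlyΨ[Trl]GlyΨ[Trl]Arg,16.53,C40H56N16O6,429.2357,429.2373,2,43.7,0.5,,,,
16,arm,Har-Lys-GlyΨ[Trl]GlyΨ[Trl]Arg,13.05,C25H46N16O4,635.3961,635.3991,1,36.5,1.4,,,,
17,arm,Dab(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg,12.46,C23H42N16O4,607.3648,607.3675,1,41.3,0.5,,,,
18,arm,Dap(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg,11.92,C22H40N16O4,593.3491,593.3517,1,25.3,3.5,,,,
19,arm,Har-6Ahx-GlyΨ[Trl]GlyΨ[Trl]]Arg,16.83,C25H45N15O4,620.3852,620.3878,1,30.5,0.6,,,,
20,arm,Har-5Ava-GlyΨ[Trl]GlyΨ[Trl]Arg,15.23,C24H43N15O4,606.3695,606.3721,1,29.7,1.8,,,,
21,arm,Har-Ala-GlyΨ[Trl]GlyΨ[Trl]]Arg,13.46,C22H39N15O4,578.3382,578.3406,1,27.8,2.1,,,,
22,arm,Har-Gly-GlyΨ[Trl]GlyΨ[Trl]Arg,13.06,C21H37N15O4,564.3226,564.3244,1,35.7,1.6,,,,
23,arm,Har-GlyΨ[Trl]GlyΨ[Trl]Arg,13.06,C19H34N14O3,507.3020,507.3011,1,20.0,2.1,,,,
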