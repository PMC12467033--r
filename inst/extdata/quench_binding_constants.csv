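enzyme,compound,temperature_k,ksv_1e4_l_per_mol,n_sites,ka_1e5_l_per_mol
alpha_amylase,TAPP,298,4.07,1.48,52.90
alpha_amylase,TAPP,304,3.37,1.40,21.79
alpha_amylase,TAPP,310,3.07,1.31,7.46
alpha_amylase,THPP,298,8.90,1.19,5.65
alpha_amylase,THPP,304,8.20,1.16,3.65
alpha_amylase,THPP,310,7.64,1.12,2.46
alpha_amylase,TCPP,298,4.04,1.36,12.54
alpha_amylase,TCPP,304,3.55,1.28,5.01
alpha_amylase,TCPP,310,3.01,1.20,2.18
alpha_amylase,Fe-TCPP,298,4.32,1.65,944.30
alpha_amylase,Fe-TCPP,304,3.36,1.38,40.38
alpha_amylase,Fe-TCPP,310,3.29,1.05,2.13
alpha_amylase,Ni-TCPP,298,9.78,1.44,99.31
alpha_amylase,Ni-TCPP,304,8.47,1.19,5.75
alpha_amylase,Ni-TCPP,310,7.11,0.99,0.61
alpha_amylase,Cu-TCPP,298,4.37,0.93,0.20
alpha_amylase,Cu-TCPP,304,4.33,0.84,0.10
alpha_amylase,Cu-TCPP,310,4.32,0.78,0.06
alpha_glucosidase,THPP,298,7.40,1.29,15.49
alpha_glucosidase,THPP,304,6.97,1.23,8.01
alpha_glucosidase,THPP,310,6.69,1.16,3.39
alpha_glucosidase,Ni-TCPP,298,17.73,1.03,2.34
alpha_glucosidase,Ni-TCPP,304,14.23,1.04,2.09
alpha_glucosidase,Ni-TCPP,310,12.31,1.03,1.83
alpha_glucosidase,Fe-TCPP,298,14.52,1.01,1.65
alpha_glucosidase,Fe-TCPP,304,13.18,1.00,1.26
alpha_glucosidase,Fe-TCPP,310,12.20,0.98,1.02
alpha_glucosidase,TCPP,298,7.45,1.30,13.73
alpha_glucosidase,TCPP,304,4.90,1.19,3.17
alpha_glucosidase,TCPP,310,4.22,1.07,0.97
alpha_glucosidase,Cu-TCPP,298,7.35,1.44,55.21
alpha_glucosidase,Cu-TCPP,304,6.74,1.25,7.38
alpha_glucosidase,Cu-TCPP,310,5.05,1.03,0.69
alpha_glucosidase,TAPP,298,6.25,1.14,2.78
alpha_glucosidase,TAPP,304,5.71,1.09,1.42
alpha_glucosidase,TAPP,310,5.66,1.01,0.65
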