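enzyme,compound,inhibitor_ug_per_ml,km_app_mmol_per_l,vmax_app_dod_per_min
alpha_amylase,TAPP,0,3.9047,0.1826
alpha_amylase,TAPP,2,4.3893,0.1670
alpha_amylase,TAPP,4,4.8719,0.1562
alpha_amylase,TAPP,6,5.1449,0.1425
alpha_amylase,TAPP,8,5.4460,0.1328
alpha_amylase,TAPP,10,5.7081,0.1243
alpha_amylase,THPP,0,3.6644,0.1390
alpha_amylase,THPP,20,7.8640,0.0740
alpha_amylase,THPP,30,8.0378,0.0580
alpha_amylase,THPP,40,8.3899,0.0491
alpha_amylase,THPP,50,8.6487,0.0426
alpha_amylase,THPP,60,8.8467,0.0376
alpha_amylase,TCPP,0,2.5848,0.1244
alpha_amylase,TCPP,25,4.9029,0.1046
alpha_amylase,TCPP,50,6.3562,0.0872
alpha_amylase,TCPP,100,8.8655,0.0709
alpha_amylase,TCPP,150,10.3380,0.0583
alpha_amylase,TCPP,200,11.3676,0.0496
alpha_amylase,Fe-TCPP,0,2.4394,0.1387
alpha_amylase,Fe-TCPP,25,2.7329,0.1143
alpha_amylase,Fe-TCPP,50,2.9384,0.0972
alpha_amylase,Fe-TCPP,100,3.2079,0.0748
alpha_amylase,Fe-TCPP,150,3.3360,0.0601
alpha_amylase,Fe-TCPP,200,3.4920,0.0512
alpha_amylase,Ni-TCPP,0,3.6368,0.1831
alpha_amylase,Ni-TCPP,40,3.6229,0.1456
alpha_amylase,Ni-TCPP,80,3.6134,0.1238
alpha_amylase,Ni-TCPP,120,3.6072,0.1032
alpha_amylase,Ni-TCPP,160,3.6027,0.0901
alpha_amylase,Ni-TCPP,200,3.5987,0.0799
alpha_amylase,Cu-TCPP,0,2.5129,0.1155
alpha_amylase,Cu-TCPP,25,2.8021,0.1101
alpha_amylase,Cu-TCPP,50,3.1685,0.1050
alpha_amylase,Cu-TCPP,100,3.5949,0.0923
alpha_amylase,Cu-TCPP,150,3.9016,0.0860
alpha_amylase,Cu-TCPP,200,4.2470,0.0785
alpha_glucosidase,THPP,0,6.7070,0.2310
alpha_glucosidase,THPP,1,7.1219,0.1528
alpha_glucosidase,THPP,2.5,7.3949,0.1013
alpha_glucosidase,THPP,5,7.5880,0.0649
alpha_glucosidase,THPP,7.5,7.6790,0.0489
alpha_glucosidase,THPP,10,7.7319,0.0377
alpha_glucosidase,Ni-TCPP,0,2.0514,0.1649
alpha_glucosidase,Ni-TCPP,5,3.0491,0.1036
alpha_glucosidase,Ni-TCPP,7.5,3.3243,0.0909
alpha_glucosidase,Ni-TCPP,10,3.5279,0.0791
alpha_glucosidase,Ni-TCPP,15,3.8090,0.0628
alpha_glucosidase,Ni-TCPP,25,4.1248,0.0444
alpha_glucosidase,Fe-TCPP,0,1.4377,0.1076
alpha_glucosidase,Fe-TCPP,16,2.6958,0.0771
alpha_glucosidase,Fe-TCPP,32,3.3979,0.0601
alpha_glucosidase,Fe-TCPP,48,3.9231,0.0502
alpha_glucosidase,Fe-TCPP,64,4.1566,0.0416
alpha_glucosidase,Fe-TCPP,80,4.3847,0.0361
alpha_glucosidase,TCPP,0,1.8019,0.1499
alpha_glucosidase,TCPP,5,2.5045,0.1369
alpha_glucosidase,TCPP,25,4.4087,0.1016
alpha_glucosidase,TCPP,50,5.5731,0.0745
alpha_glucosidase,TCPP,100,7.1021,0.0516
alpha_glucosidase,TCPP,150,7.7894,0.0389
alpha_glucosidase,Cu-TCPP,0,2.7842,0.1689
alpha_glucosidase,Cu-TCPP,5,3.3657,0.1496
alpha_glucosidase,Cu-TCPP,10,3.8284,0.1344
alpha_glucosidase,Cu-TCPP,25,4.7824,0.1028
alpha_glucosidase,Cu-TCPP,50,5.4948,0.0718
alpha_glucosidase,Cu-TCPP,100,6.4626,0.0473
alpha_glucosidase,TAPP,0,2.0896,0.0969
alpha_glucosidase,TAPP,12.5,3.9347,0.0791
alpha_glucosidase,TAPP,15,4.2527,0.0767
alpha_glucosidase,TAPP,17.5,4.5048,0.0736
alpha_glucosidase,TAPP,20,4.7611,0.0711
alpha_glucosidase,TAPP,22.5,5.0007,0.0688
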