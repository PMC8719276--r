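cause,t_year,best,worst
tracheal_bronchus_lung,1,0.7579,0.4959
tracheal_bronchus_lung,2,0.5743,0.246
tracheal_bronchus_lung,3,0.4353,0.122
tracheal_bronchus_lung,4,0.3299,0.0605
tracheal_bronchus_lung,5,0.25,0.03
tracheal_bronchus_lung,6,0.1895,0.0149
tracheal_bronchus_lung,7,0.1436,0.0074
tracheal_bronchus_lung,8,0.1088,0.0037
tracheal_bronchus_lung,9,0.0825,0.0018
tracheal_bronchus_lung,10,0.0625,9e-04
colon_rectum,1,0.9175,0.631
colon_rectum,2,0.8417,0.3981
colon_rectum,3,0.7722,0.2512
colon_rectum,4,0.7085,0.1585
colon_rectum,5,0.65,0.1
colon_rectum,6,0.5963,0.0631
colon_rectum,7,0.5471,0.0398
colon_rectum,8,0.502,0.0251
colon_rectum,9,0.4605,0.0158
colon_rectum,10,0.4225,0.01
stomach,1,0.8106,0.5493
stomach,2,0.6571,0.3017
stomach,3,0.5326,0.1657
stomach,4,0.4318,0.091
stomach,5,0.35,0.05
stomach,6,0.2837,0.0275
stomach,7,0.23,0.0151
stomach,8,0.1864,0.0083
stomach,9,0.1511,0.0046
stomach,10,0.1225,0.0025
breast,1,0.9791,0.786
breast,2,0.9587,0.6178
breast,3,0.9387,0.4856
breast,4,0.9192,0.3817
breast,5,0.9,0.3
breast,6,0.8812,0.2358
breast,7,0.8629,0.1853
breast,8,0.8449,0.1457
breast,9,0.8272,0.1145
breast,10,0.81,0.09
liver,1,0.7248,0.4573
liver,2,0.5253,0.2091
liver,3,0.3807,0.0956
liver,4,0.2759,0.0437
liver,5,0.2,0.02
liver,6,0.145,0.0091
liver,7,0.1051,0.0042
liver,8,0.0761,0.0019
liver,9,0.0552,9e-04
liver,10,0.04,4e-04
default,1,0.8873,0.6034
default,2,0.7873,0.3641
default,3,0.6986,0.2197
default,4,0.6199,0.1326
default,5,0.55,0.08
default,6,0.488,0.0483
default,7,0.433,0.0291
default,8,0.3842,0.0176
default,9,0.3409,0.0106
default,10,0.3025,0.0064
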