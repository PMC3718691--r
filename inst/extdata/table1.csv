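vesicle,region,N_v,Avg,SD
1,rest,72082,581,41
1,nubs-ribs,1658,558,40
1,nubs-spars,512,565,40
1,nubs-booms,1432,578,42
1,nubs-pins,610,561,42
1,nubs-nonAZM,1653,560,40
2,rest,76582,500,105
2,nubs-ribs,652,483,99
2,nubs-spars,310,466,82
2,nubs-booms,568,445,86
2,nubs-pins,584,415,85
2,nubs-nonAZM,2130,431,90
3,rest,70993,481,102
3,nubs-ribs,914,444,96
3,nubs-spars,598,424,95
3,nubs-booms,1126,438,89
3,nubs-pins,772,418,93
3,nubs-nonAZM,2264,417,85
4,rest,77597,486,97
4,nubs-ribs,791,433,85
4,nubs-spars,389,425,82
4,nubs-booms,1259,425,88
4,nubs-pins,804,430,83
4,nubs-nonAZM,1330,420,89
5,rest,69063,491,103
5,nubs-ribs,649,438,79
5,nubs-spars,559,443,97
5,nubs-booms,931,407,89
5,nubs-pins,547,421,74
5,nubs-nonAZM,995,391,90
6,rest,64417,460,86
6,nubs-ribs,759,413,77
6,nubs-spars,362,401,70
6,nubs-booms,1150,391,85
6,nubs-pins,555,400,84
6,nubs-nonAZM,1764,397,88
7,rest,72812,432,87
7,nubs-ribs,911,370,76
7,nubs-spars,220,377,71
7,nubs-booms,786,373,76
7,nubs-pins,259,364,77
7,nubs-nonAZM,663,356,75
8,rest,81576,625,19
8,nubs-ribs,680,605,17
8,nubs-spars,325,607,15
8,nubs-booms,707,608,15
8,nubs-pins,575,601,16
8,nubs-nonAZM,951,610,12
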