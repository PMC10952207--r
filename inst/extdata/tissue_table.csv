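label,name,conductivity_S_per_m,rel_permittivity,density_kg_per_m3,t1w_mean,t1w_sd,dsc_group
0,air,0,1,0,0,0,air
1,skin,0.64,49.9,1109,800,40,skin
2,fat,0.077,11.7,911,1000,50,fat
3,muscle,0.77,58.2,1090,500,30,muscle
4,skull,0.083,13.4,1908,150,20,skull
5,csf,2.22,72.7,1007,200,15,csf
6,gray_matter,0.69,60.0,1045,450,25,gray matter
7,white_matter,0.41,43.8,1041,650,30,white matter
8,cerebellum,0.72,59.8,1045,480,25,cerebellum
9,cancellous_bone,0.18,23.2,1178,300,25,skull
10,dura,0.83,60.0,1174,350,25,dura
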