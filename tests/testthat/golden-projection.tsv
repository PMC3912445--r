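step	length	weight	abundance	biomass	removed_biomass
0	10	10.4	1e+06	10400000	0
1	17.62	56.8919803712	8e+05	45513584.29696	11378396.07424
2	22.954	125.779096629306	640000	80498621.8427556	20124655.4606889
3	26.6878	197.684064721189	512000	101214241.137249	25303560.2843121
4	29.30146	261.638180685136	409600	107166998.808632	26791749.7021579
5	31.131022	313.771485916936	327680	102816640.505262	25704160.1263154
6	32.4117154	354.110977139691	262144	92828067.9913072	23207016.9978268
7	33.30820078	384.314580082244	209715.2	80596609.0248639	20149152.256216
8	33.935740546	406.448318998598	167772.16	68190712.4067638	17047678.1016909
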