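year	1	2	3	4	5	6	7	8	9
1985	102.74191689429334	NA	NA	NA	NA	NA	NA	NA	NA
1986	98.870603657207823	142.6732907854022	NA	NA	NA	NA	NA	NA	NA
1987	100.72625682267469	135.32227859777532	170.14116528848075	NA	NA	NA	NA	NA	NA
1988	101.26572520992208	137.54242246636525	172.91434939834519	224.32164724918556	NA	NA	NA	NA	NA
1989	100.80853664628199	137.83335732721267	174.27538692252992	226.54941024659593	261.34108791116142	NA	NA	NA	NA
1990	99.787750967817033	139.37190079614015	169.62406173678758	222.10548264185329	264.94328605177742	291.60745649458289	NA	NA	NA
1991	103.02304399487788	137.53149415716786	169.97046123446214	223.97058198324098	262.45486364762667	292.41293263211054	310.60974473950415	NA	NA
1992	99.810681923173803	132.78708915819044	166.95867382961043	223.83768481164694	266.96585252344249	291.23402077315814	312.0150606973952	324.08416912708037	NA
1993	104.03684742775408	133.21906614284896	171.40519470966254	220.71108470010671	263.21475759477329	285.06817483369412	311.77950563658129	321.38508135518066	334.27633642214232
1994	99.874571801895158	140.74022669146038	169.20501024807976	225.61174521378447	265.3889457668044	291.6241209070613	311.37980482573369	320.95707215270431	334.05318998601649
1995	102.60973930844698	137.48672281184304	171.39590024648243	225.9514972004005	264.72150053040792	290.31988571451802	307.85181062286426	326.18204796960987	335.19387651686856
1996	NA	134.53738313203999	171.89467467445763	224.81738540290263	262.50997211823926	291.4248161297312	309.75767572677859	323.67247682506405	331.45729591889062
1997	NA	NA	172.55520704393982	227.055826471399	267.22910503958394	292.21800245473099	311.18508482399909	323.33351440831916	333.71034088645263
1998	NA	NA	NA	224.08609034584683	265.36344861143465	293.85382865458536	308.03100178445527	322.91484087492182	335.19186467778002
1999	NA	NA	NA	NA	264.25717129319924	289.59977088105103	308.85239087085228	320.76797615967894	330.18806600610418
2000	NA	NA	NA	NA	NA	293.65944026408829	311.10004149536337	324.38062774608079	330.68805859124433
2001	NA	NA	NA	NA	NA	NA	311.47440597566919	322.72235425850698	330.14616640329245
2002	NA	NA	NA	NA	NA	NA	NA	322.79112053733616	329.49121576599521
2003	NA	NA	NA	NA	NA	NA	NA	NA	332.56960887148233
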