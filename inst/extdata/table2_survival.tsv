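# Published per-probeset univariate Cox hazard ratios and 95% Wald intervals
# for the concordant genes associated with overall survival, by treatment
# arm; `*_significant` reproduces the printed asterisks and must agree with
# the interval excluding 1. `direction` is the gene's expression direction.
gene_symbol	probeset_id	direction	chop_hr	chop_ci_low	chop_ci_high	chop_significant	rchop_hr	rchop_ci_low	rchop_ci_high	rchop_significant	arm_diff_p
CCT3	200910_at	1	1.686	1.057	2.689	TRUE	1.682	0.999	2.832	FALSE	0.9944
CLCF1	219500_at	-1	0.846	0.685	1.045	FALSE	0.736	0.61	0.889	TRUE	0.3366
COBLL1	203641_s_at	-1	0.86	0.767	0.963	TRUE	0.976	0.872	1.092	FALSE	0.1204
COBLL1	229598_at	-1	0.855	0.76	0.961	TRUE	0.849	0.738	0.976	TRUE	0.9388
CTPS	202613_at	1	1.451	1.007	2.091	TRUE	1.476	1.034	2.106	TRUE	0.9475
FABP5	202345_s_at	1	1.144	0.836	1.566	FALSE	1.468	1.081	1.995	TRUE	0.2645
HSPD1	200806_s_at	1	1.267	0.739	2.174	FALSE	1.886	1.115	3.19	TRUE	0.3012
HSPD1	200807_s_at	1	1.12	0.88	1.425	FALSE	1.614	1.059	2.459	TRUE	0.1401
MRPS17	218982_s_at	1	1.264	0.879	1.818	FALSE	1.787	1.18	2.707	TRUE	0.2186
NDC80	204162_at	1	1.153	0.848	1.568	FALSE	1.54	1.052	2.255	TRUE	0.2464
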