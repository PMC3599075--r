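probe_id	gene_symbol	is_control	c1_r01_AF3	c1_r01_AF5	c1_r02_AF3	c1_r02_AF5	c10_r01_AF3	c10_r01_AF5	c10_r02_AF3	c10_r02_AF5
P001	AR	FALSE	2359.77	3516.8600000000001	3798.1999999999998	3755.7399999999998	3885.3800000000001	2904.5599999999999	2610.6799999999998	739.72000000000003
P002	KLK3	FALSE	75.430000000000007	2631.9099999999999	329.64999999999998	999	2352.5900000000001	2276.6500000000001	3329.9899999999998	728.19000000000005
P003	EPCAM	FALSE	1203.21	1950.1900000000001	3028.5100000000002	2279.75	3850.3299999999999	1578.9000000000001	1948.72	3574.48
P004	TMPRSS2	FALSE	1138.4000000000001	3885.2800000000002	1172.5599999999999	756.36000000000001	3056.3400000000001	2993.8800000000001	3373.3200000000002	2983.5999999999999
P005	FKBP5	FALSE	3261.75	1861.7	436.20999999999998	3621.8200000000002	2869.4499999999998	3585.8699999999999	2074.2600000000002	2261.5
P006	ACPP	FALSE	1071.29	2503.3400000000001	3818.1100000000001	373.79000000000002	3986.5900000000001	3243.9400000000001	2137.9200000000001	322.08999999999997
P007	ACTB	FALSE	2908.6500000000001	1578.1400000000001	1685.8	3608.6399999999999	2044.8299999999999	3281.4400000000001	2285.7600000000002	3420.1999999999998
P008		TRUE	3628.1199999999999	66.109999999999999	1842.21	3570.7800000000002	1980.1800000000001	1707.95	986.24000000000001	3658.3000000000002
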