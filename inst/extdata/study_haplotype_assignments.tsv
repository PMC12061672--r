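sample_id	country	length	structure	lineage	haplotype	status
Eth1	ETH	839	P0Q2	A	A1-839-6-ETH	novel
Eth4	ETH	820	P0Q2	A	A2-820-5-ETH	novel
Eth5	ETH	818	P0Q2	A	A3-818-5-ETH	novel
Jor1	JOR	837	P0Q2	A	A1-837-6-USA	known
Oma1	OMN	838	P0Q2	A	A1-838-6-OMN	novel
Oma2	OMN	838	P0Q2	A	A1-838-6-OMN	novel
Sau13	SAU	838	P0Q2	A	KSA4e	known
Sau14	SAU	838	P0Q2	A	KSA4e	known
Sau15	SAU	837	P0Q2	A	KSA6b	known
Sau16	SAU	837	P0Q2	A	KSA6d	known
Sau17	SAU	838	P0Q2	A	KSA4f	known
Sau20	SAU	838	P0Q2	A	A1-838-6-SAU	novel
Yem2	YEM	836	P0Q2	A	A1-836-6-YEM	novel
Yem4	YEM	818	P0Q2	A	A2-818-6-YEM	novel
Yem8	YEM	836	P0Q2	A	A3-836-6-YEM	novel
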