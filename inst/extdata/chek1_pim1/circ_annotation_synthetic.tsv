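circ_id	host_gene	chrom	start	end	spliced_length
hsa_circ_0024791	CHEK1	chr11	125495031	125497890	612
hsa_circ_0024793	CHEK1	chr11	125496210	125501480	1048
hsa_circ_0024794	CHEK1	chr11	125497005	125503940	1385
hsa_circ_0076213	PIM1	chr6	37138105	37139620	423
hsa_circ_0076214	PIM1	chr6	37138105	37140892	760
hsa_circ_0076215	PIM1	chr6	37137021	37140892	1102
hsa_circ_0076216	PIM1	chr6	37137021	37141455	1366
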