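accession	label	start	end	sequence	source
P43238	Arah1_ep1	294	303	TPGQFEDFFP	literature
P43238	Arah1_ep2	325	334	FNAEFNEIRR	literature
P43238	Arah1_ep3	461	470	GTGNLELVAV	literature
P43238	Arah1_ep4	89	98	GERTRGRQPG	literature
P43238	Arah1_ep5	551	560	IDOIEKOAKD	literature
Q6PSU2	Arah2_ep1	42	51	LRPCEQHLMQ	literature
O82580	Arah3_ep1	29	44	IETWNPNNQEFECAG	literature
Q647G9	Arah6_ep1	83	90	LNEMENTQ	literature
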