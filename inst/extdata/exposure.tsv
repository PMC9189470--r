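SNP	effect_allele	other_allele	eaf	beta	se	pval	samplesize
rs5194191	A	C	0.176459084032103	0.0586579089668666	0.02096634532005	0.00514651208529553	7827
rs7693232	A	C	0.209569521050435	0.072028498269464	0.0196377368321195	0.000244587633231704	7827
rs0519113	A	G	0.274922965432052	0.0388310532085077	0.0179015135032667	0.0300713604988557	7827
rs5459399	C	T	0.227904953388497	0.132757492506248	0.0190535134074409	3.22365337241545e-12	7827
rs3369865	C	T	0.133845831244253	0.0786731478356471	0.023474011373419	0.00080375054831816	7827
rs3632496	C	T	0.287654437788296	0.0768183185284605	0.0176565738193573	1.35708422402468e-05	7827
rs4003081	A	C	0.324075850553345	0.105580344793219	0.0170771352839052	6.30719354256946e-10	7827
rs6819852	G	T	0.326148582471069	0.106612953006408	0.0170489451856231	4.01750734693538e-10	7827
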