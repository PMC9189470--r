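SNP	effect_allele	other_allele	eaf	beta	se	pval	samplesize
rs5194191	A	C	0.176459084032103	0.00275733149012427	0.0243218167136659	0.909738294302483	196000
rs7693232	A	C	0.209569521050435	-0.00206669301848864	0.0227805766150987	0.927713714336428	196000
rs0519113	A	G	0.274922965432052	-0.0137906001610327	0.0207664866564656	0.506639365728567	196000
rs5459399	C	T	0.227904953388497	-0.0211747655031347	0.022102853586218	0.338057471036661	196000
rs3369865	C	T	0.133845831244253	0.0160087151512385	0.0272308117339281	0.556606295656175	196000
rs3632496	C	T	0.287654437788296	-0.00176930286358669	0.0204823466212325	0.931162879637616	196000
rs4003081	A	C	0.324075850553345	-0.0253460750450869	0.0198101742592413	0.200739567296766	196000
rs6819852	G	T	0.326148582471069	0.0262012729067912	0.019777472594116	0.185236199586654	196000
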