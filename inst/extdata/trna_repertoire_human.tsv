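# Human-like tRNA gene repertoire (gtRNAdb-style). The anticodon presence/
# absence structure matches the human genome (48 isoacceptors, 506 tRNA
# genes; mono-isoacceptor amino acids: Phe, Asp, His, Cys); per-anticodon
# gene counts are representative values, not a frozen census snapshot.
anticodon	aa	gene_count
AGC	A	35
CGC	A	5
TGC	A	10
ACG	R	7
CCG	R	4
TCG	R	6
CCT	R	5
TCT	R	6
GTT	N	29
ATT	N	1
GTC	D	18
GCA	C	30
CTG	Q	22
TTG	Q	11
CTC	E	8
TTC	E	13
GCC	G	16
CCC	G	5
TCC	G	9
GTG	H	12
AAT	I	16
GAT	I	3
TAT	I	5
AAG	L	11
CAG	L	9
CAA	L	7
TAA	L	4
TAG	L	3
CTT	K	17
TTT	K	11
CAT	M	21
GAA	F	14
AGG	P	10
CGG	P	4
TGG	P	7
AGA	S	13
CGA	S	4
TGA	S	5
GCT	S	8
AGT	T	10
CGT	T	6
TGT	T	6
CCA	W	10
GTA	Y	15
ATA	Y	1
AAC	V	11
CAC	V	18
TAC	V	5
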