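name	motif	cut_offset	rules
Alw44I	GTGCAC	1	6|any|no cut if the 3'-cytosine is methylated in at least one strand
XmiI	GTMKAC	2	6|both|blocked when the 3'-cytosine is methylated on both strands
BsuRI	GGCC	2	3|any|blocked if the inner cytosine is methylated in at least one strand
Bsh1236I	CGCG	2	1,3|any|activity blocked by hemimethylation of either cytosine
Hin6I	GCGC	1	2|both|no cut if the recognition sequence is methylated on both strands
Eco47I	GGWCC	1	5|any|hemimethylation of the 3'-cytosine blocks cleavage;4|any|methylation of the inner cytosine also blocks cleavage
MspI	CCGG	1	1|any|methylation of one strand (outer cytosine) suffices to block
BamHI	GGATCC	1	5,6|any|methylation of one strand suffices to block (all site cytosines watched)
NcoI	CCATGG	1	1,2|any|methylation of one strand suffices to block (all site cytosines watched)
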