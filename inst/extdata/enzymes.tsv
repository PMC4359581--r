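# gbskit enzyme annotation file
# name<TAB>recognition (with optional ^ cut marker)<TAB>optional remnant
ApeKI	G^CWGC	CWGC
PstI	CTGCA^G	TGCAG
EcoRI	G^AATTC	AATTC
MspI	C^CGG	CGG
SbfI	CCTGCA^GG	TGCAGG
EcoT22I	ATGCA^T	TGCAT
NsiI	ATGCA^T	TGCAT
ApoI	R^AATTY	AATTY
BamHI	G^GATCC	GATCC
HindIII	A^AGCTT	AGCTT
SphI	GCATG^C	CATGC
NlaIII	CATG^	CATG
MseI	T^TAA	TAA
MluCI	^AATT	AATT
TaqI	T^CGA	CGA
AgeI	A^CCGGT	CCGGT
AluI	AG^CT	CT
KpnI	GGTAC^C	GTACC
SacI	GAGCT^C	AGCTC
SalI	G^TCGAC	TCGAC
XbaI	T^CTAGA	CTAGA
XhoI	C^TCGAG	TCGAG
NdeI	CA^TATG	TATG
NcoI	C^CATGG	CATGG
AvaII	G^GWCC	GWCC
HinfI	G^ANTC	ANTC
DdeI	C^TNAG	TNAG
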