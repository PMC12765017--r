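gene	sample_id	hgvsp	pipeline	pathways	detection_sources	breed
MSH3	TC1020	p.M282R	RNA	MMR	rna,wes_tumor,wes_normal	Beagle
SIRT6	TC1241	p.R145H	RNA	BER,DSBR	rna,wes_tumor,wes_normal	Border Collie
KAT5	TC67	p.I531L	RNA	DSBR	rna,wes_tumor,wes_normal	Dachshund
NSD2	TC2402	p.A1309T	RNA	DSBR	rna,wes_tumor,wes_normal	Labrador Retriever
MLH3	TC1123	p.S1103Y	RNA	MMR	rna,wes_tumor,wes_normal	Malamute
NEIL1	TC1088	p.W296*	RNA	BER	rna,wes_tumor,wes_normal	Mix
TIMELESS	TC1088	p.Q1283*	RNA	DSBR	rna,wes_tumor,wes_normal	Mix
POLQ	TC538	p.R793*	RNA	BER,DSBR	rna,wes_tumor,wes_normal	Mix
MDC1	TC1164	p.R1649Q	RNA	DSBR	rna,wes_tumor,wes_normal	Mix
ERCC4	TC1473	p.H201Q	RNA	DSBR,NER	rna,wes_tumor,wes_normal	Mix
MCM9	TC2288	p.R450K	RNA	MMR	rna,wes_tumor,wes_normal	Mix
MUTYH	TC22	p.R658W	WES	BER,MMR	rna,wes_tumor	Beagle
MSH6	TC22	p.R990H	WES	MMR	wes_tumor	Beagle
MSH6	TC22	p.E998D	WES	MMR	wes_tumor	Beagle
DCLRE1C	TC2110	p.G207Efs*20	WES	DSBR	rna,wes_tumor	Labrador Retriever
BARD1	TC2089	p.Q542del	WES	DSBR	wes_tumor	Labrador Retriever
BARD1	TC1123	p.L654F	WES	DSBR	wes_tumor	Malamute
MUS81	TC538	p.H375N	WES	DSBR	wes_tumor	Mix
ACD	TC2288	p.V266I	WES	BER	wes_tumor	Mix
POLD3	TC67	p.A362Sfs*5	RNA	BER,DSBR,MMR,NER	rna	Dachshund
POT1	TC902	p.M711L	RNA	BER	rna	German Shepherd
RIF1	TC2402	p.I2399L	RNA	DSBR	rna	Labrador Retriever
ATM	TC627	p.K687Q	RNA	DSBR	rna	Labrador Retriever
MRE11	TC2289	p.L286V	RNA	DSBR	rna	Labrador Retriever
TP53	TC1593	p.I247L	RNA	DSBR,NER	rna	Portuguese Water Dog
LIG1	TC2011	p.S444R	RNA	BER,MMR	rna	Shetland Sheepdog
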