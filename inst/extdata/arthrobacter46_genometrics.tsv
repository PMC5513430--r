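phage	cluster	accession	length_bp	pct_gc	n_genes
Bennie	AK	KU160640	43075	61.4	62
DrRobert	AK	KU160643	42601	60.6	59
Glenn	AK	KU160645	44389	60.8	64
HunterDalle	AK	KU160648	43336	61.6	60
Immaculata	AK	KU160649	43661	61	62
Joann	AK	KU160652	44183	60.7	63
Korra	AK	KU160653	43707	61.1	60
Preamble	AK	KU160659	43374	60.7	64
Pumancara	AK	KU160661	42830	61.7	61
RAP15	AK	KU160662	44259	60.9	63
Vulture	AK	KU160671	43336	61.1	64
Wayne	AK	KU160672	44371	61.1	62
Laroye	AL	KU160654	60005	64.8	99
Salgado	AL	KU160664	59807	64.6	99
Circum	AM	KU160642	58353	45.2	99
Mudcat	AM	KU647628	59443	45.1	95
Decurro	AN	KT355471	15524	60.2	26
Jessica	AN	KT355473	15556	60.1	26
Maggie	AN	KU160655	15556	60.1	26
Moloch	AN	KU160657	15630	60	26
Muttlie	AN	KU160658	15524	60.2	26
Sandman	AN	KT355475	15630	60	26
Stratus	AN	KU160667	15630	60	26
Toulouse	AN	KU160670	15319	60.3	25
TymAbreu	AN	KT783672	15556	60.1	26
Yank	AN	KU160674	15524	60.2	26
Brent	AO	KT365401	49879	63.4	74
Jawnski	AO	KU160651	49419	63.4	73
BarretLemon	AO	KU647629	51290	60.9	79
Martha	AO	KU160656	51027	61	77
Sonny	AO	KU160665	50909	61.1	77
TaeYoung	AO	KU160668	50999	61	78
Tank	AP	KU160669	67592	62.9	105
Wilde	AP	KU160673	68203	62.9	109
Amigo	AQ	KU160638	59173	52.9	86
Anansi	AQ	KU160639	58848	53	86
Gorgeous	AQ	KU160647	58979	53	86
Rings	AQ	KU160663	59167	53	86
SorJuana	AQ	KU160666	58979	53	86
KellEzio	AT	KU647626	58871	63.3	99
Kitkat	AT	KU647627	58560	63.4	100
CapnMurica	AU	KU160641	58159	49.6	88
Gordon	AU	KU160646	58279	49.8	89
PrincessTrina	AR	KU160660	70265	61.6	112
Galaxy	Singleton	KU160644	37809	68.4	65
Jasmine	Singleton	KU160650	46723	45.9	58
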