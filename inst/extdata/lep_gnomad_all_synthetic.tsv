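variant_id	chrom	pos	ref	alt	consequence	population	sex	ac	an	nhom	sift	polyphen2	mutationtaster	fathmm_mkl	provean	lof_confidence	clinvar
rs17151919	7	127894013	C	T	missense	ALL	ALL	2377	282912	105	tolerated	benign	benign	neutral	neutral		benign
lepv001	7	127894026	C	T	missense	ALL	ALL	20	282912	0	tolerated	benign	benign	neutral	neutral		uncertain
lepv002	7	127894039	C	T	missense	ALL	ALL	15	282912	0	tolerated	benign	benign	neutral	neutral		uncertain
lepv003	7	127894052	C	T	missense	ALL	ALL	10	282912	0	tolerated	benign	benign	neutral	neutral		
lepv004	7	127894065	C	T	missense	ALL	ALL	8	282912	0	tolerated	benign	benign	neutral	neutral		
lepv005	7	127894078	C	T	missense	ALL	ALL	6	282912	0	tolerated	benign	benign	neutral	neutral		
lepv006	7	127894091	C	T	missense	ALL	ALL	4	282912	0	tolerated	benign	benign	neutral	neutral		
lepv007	7	127894104	C	T	missense	ALL	ALL	4	282912	0	tolerated	benign	benign	neutral	neutral		
lepv008	7	127894117	C	T	missense	ALL	ALL	3	282912	0	tolerated	benign	benign	neutral	neutral		
lepv009	7	127894130	C	T	missense	ALL	ALL	3	282912	0	tolerated	benign	benign	neutral	neutral		
lepv010	7	127894143	C	T	missense	ALL	ALL	2	282912	0	tolerated	benign	benign	neutral	neutral		
lepv011	7	127894156	C	T	missense	ALL	ALL	2	282912	0	tolerated	benign	benign	neutral	neutral		
lepv012	7	127894169	C	T	missense	ALL	ALL	2	282912	0	tolerated	benign	benign	neutral	neutral		
lepv013	7	127894182	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	neutral	neutral		
lepv014	7	127894195	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	neutral	neutral		
lepv015	7	127894208	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	neutral	neutral		
lepv016	7	127894221	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	neutral	neutral		
lepv017	7	127894234	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	neutral	neutral		
lepv018	7	127894247	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	neutral	neutral		
lepv019	7	127894260	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	neutral	neutral		
lepv101	7	127894273	CAT	C	frameshift	ALL	ALL	2	282912	0			benign			LC	
lepv102	7	127894286	CAT	C	frameshift	ALL	ALL	1	282912	0			benign			LC	
rs1307773933	7	127894299	CAT	C	frameshift	ALL	ALL	1	282912	0			deleterious			HC	
rs747703977	7	127894312	CAT	C	inframe_deletion	ALL	ALL	1	282912	0			deleterious			HC	
lepv103	7	127894325	CAT	C	frameshift	ALL	ALL	1	282912	0			deleterious			HC	
lepv104	7	127894338	CAT	C	frameshift	ALL	ALL	1	282912	0			deleterious			HC	
lepv105	7	127894351	C	T	splice_acceptor	ALL	ALL	1	282912	0			deleterious			HC	
rs1800564	7	127894364	C	T	missense	ALL	ALL	43	282912	0	deleterious	benign	benign	neutral	neutral		
lepv111	7	127894377	C	T	missense	ALL	ALL	29	282912	0	tolerated	probably_damaging	benign	neutral	neutral		uncertain
lepv112	7	127894390	C	T	missense	ALL	ALL	20	282912	0	tolerated	benign	deleterious	neutral	neutral		uncertain
lepv113	7	127894403	C	T	missense	ALL	ALL	15	282912	0	tolerated	benign	benign	damaging	neutral		
lepv114	7	127894416	C	T	missense	ALL	ALL	10	282912	0	tolerated	benign	benign	neutral	damaging		
lepv115	7	127894429	C	T	missense	ALL	ALL	8	282912	0	deleterious	benign	benign	neutral	neutral		
lepv116	7	127894442	C	T	missense	ALL	ALL	7	282912	0	tolerated	probably_damaging	benign	neutral	neutral		
lepv117	7	127894455	C	T	missense	ALL	ALL	6	282912	0	tolerated	benign	deleterious	neutral	neutral		
lepv118	7	127894468	C	T	missense	ALL	ALL	5	282912	0	tolerated	benign	benign	damaging	neutral		
lepv119	7	127894481	C	T	missense	ALL	ALL	4	282912	0	tolerated	benign	benign	neutral	damaging		
lepv120	7	127894494	C	T	missense	ALL	ALL	3	282912	0	deleterious	benign	benign	neutral	neutral		
lepv121	7	127894507	C	T	missense	ALL	ALL	2	282912	0	tolerated	probably_damaging	benign	neutral	neutral		
lepv122	7	127894520	C	T	missense	ALL	ALL	2	282912	0	tolerated	benign	deleterious	neutral	neutral		
lepv123	7	127894533	C	T	missense	ALL	ALL	2	282912	0	tolerated	benign	benign	damaging	neutral		
lepv124	7	127894546	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	neutral	damaging		
lepv125	7	127894559	C	T	missense	ALL	ALL	1	282912	0	deleterious	benign	benign	neutral	neutral		
lepv126	7	127894572	C	T	missense	ALL	ALL	1	282912	0	tolerated	probably_damaging	benign	neutral	neutral		
lepv127	7	127894585	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	deleterious	neutral	neutral		
lepv128	7	127894598	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	damaging	neutral		
lepv129	7	127894611	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	neutral	damaging		
lepv130	7	127894624	C	T	missense	ALL	ALL	1	282912	0	deleterious	benign	benign	neutral	neutral		
lepv141	7	127894637	C	T	missense	ALL	ALL	10	282912	0	tolerated	probably_damaging	deleterious	neutral	neutral		
lepv142	7	127894650	C	T	missense	ALL	ALL	5	282912	0	tolerated	benign	deleterious	damaging	neutral		
lepv143	7	127894663	C	T	missense	ALL	ALL	4	282912	0	tolerated	benign	benign	damaging	damaging		
lepv144	7	127894676	C	T	missense	ALL	ALL	3	282912	0	deleterious	benign	benign	neutral	damaging		
lepv145	7	127894689	C	T	missense	ALL	ALL	2	282912	0	deleterious	probably_damaging	benign	neutral	neutral		
lepv146	7	127894702	C	T	missense	ALL	ALL	2	282912	0	tolerated	possibly_damaging	deleterious	neutral	neutral		
lepv147	7	127894715	C	T	missense	ALL	ALL	2	282912	0	tolerated	benign	deleterious	damaging	neutral		
lepv148	7	127894728	C	T	missense	ALL	ALL	2	282912	0	tolerated	benign	benign	damaging	damaging		
lepv149	7	127894741	C	T	missense	ALL	ALL	1	282912	0	deleterious	benign	benign	neutral	damaging		
lepv150	7	127894754	C	T	missense	ALL	ALL	1	282912	0	deleterious	possibly_damaging	benign	neutral	neutral		
lepv151	7	127894767	C	T	missense	ALL	ALL	1	282912	0	tolerated	probably_damaging	deleterious	neutral	neutral		
lepv152	7	127894780	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	deleterious	damaging	neutral		
lepv153	7	127894793	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	benign	damaging	damaging		
rs28954113	7	127894806	C	T	missense	ALL	ALL	3	282912	0	deleterious	probably_damaging	deleterious	damaging	damaging		benign
rs724159998	7	127894819	C	T	missense	ALL	ALL	1	282912	0	tolerated	probably_damaging	deleterious	damaging	neutral		
lepv161	7	127894832	C	T	missense	ALL	ALL	3	282912	0	tolerated	probably_damaging	deleterious	damaging	damaging		
lepv162	7	127894845	C	T	missense	ALL	ALL	3	282912	0	deleterious	probably_damaging	deleterious	damaging	damaging		
lepv163	7	127894858	C	T	missense	ALL	ALL	2	282912	0	deleterious	benign	benign	damaging	damaging		
lepv164	7	127894871	C	T	missense	ALL	ALL	2	282912	0	deleterious	probably_damaging	deleterious	neutral	damaging		
lepv165	7	127894884	C	T	missense	ALL	ALL	2	282912	0	deleterious	probably_damaging	deleterious	damaging	damaging		
lepv166	7	127894897	C	T	missense	ALL	ALL	2	282912	0	tolerated	possibly_damaging	deleterious	damaging	neutral		
lepv167	7	127894910	C	T	missense	ALL	ALL	2	282912	0	deleterious	benign	deleterious	damaging	damaging		
lepv168	7	127894923	C	T	missense	ALL	ALL	2	282912	0	deleterious	probably_damaging	deleterious	damaging	damaging		
lepv169	7	127894936	C	T	missense	ALL	ALL	2	282912	0	deleterious	possibly_damaging	benign	neutral	damaging		
lepv170	7	127894949	C	T	missense	ALL	ALL	1	282912	0	deleterious	probably_damaging	deleterious	damaging	neutral		
lepv171	7	127894962	C	T	missense	ALL	ALL	1	282912	0	deleterious	probably_damaging	deleterious	damaging	damaging		
lepv172	7	127894975	C	T	missense	ALL	ALL	1	282912	0	tolerated	benign	deleterious	damaging	damaging		
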