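sample_id	gene	protein_position	consequence	pathogenicity
S001	TTN	16200	p.Gln16200Ter	pathogenic
S001	LMNA	190	p.Arg190Trp	pathogenic
S002	TTN	34500	p.Glu34500Ter	likely_pathogenic
S002	DSP	1215	p.Gln1215Ter	likely_pathogenic
S003	TTN	17000	p.Ser17000GlyfsTer6	novel_truncating
S004	TTN	18038	p.Trp18038Ter	pathogenic
S005	TTN	19075	p.Lys19075LeufsTer8	likely_pathogenic
S005	RAF1	261	p.Ser261Leu	pathogenic
S006	TTN	20112	p.Gly20112Ter	novel_truncating
S007	TTN	21150	p.Tyr21150ArgfsTer10	pathogenic
S008	TTN	22188	p.Leu22188Ter	likely_pathogenic
S009	TTN	23225	p.Cys23225GlufsTer3	novel_truncating
S010	TTN	24262	p.Arg24262Ter	pathogenic
S011	TTN	25300	p.Gln25300TrpfsTer5	likely_pathogenic
S011	TRPM4	914	p.Gly914Ser	likely_pathogenic
S012	TTN	26338	p.Glu26338Ter	novel_truncating
S013	TTN	27375	p.Ser27375GlyfsTer7	pathogenic
S014	TTN	28412	p.Trp28412Ter	likely_pathogenic
S015	TTN	29450	p.Lys29450LeufsTer9	novel_truncating
S016	TTN	30488	p.Gly30488Ter	pathogenic
S017	TTN	31525	p.Tyr31525ArgfsTer11	likely_pathogenic
S018	TTN	32562	p.Leu32562Ter	novel_truncating
S019	TTN	33600	p.Cys33600Ter	pathogenic
S020	LMNA	220	p.Gln220Gln	pathogenic
S021	LMNA	221	p.Tyr221Lys	pathogenic
S022	LMNA	222	p.Glu222Trp	pathogenic
S023	DSP	923	p.Lys923Lys	likely_pathogenic
S024	DSP	924	p.Leu924Gly	likely_pathogenic
S025	DSP	925	p.Trp925Glu	likely_pathogenic
S026	BAG3	96	p.Leu96Gly	pathogenic
S027	BAG3	97	p.Leu97Ser	pathogenic
S028	FKTN	107	p.Arg107Trp	likely_pathogenic
S029	LAMA2	114	p.Lys114Cys	pathogenic
S030	MYBPC3	121	p.Tyr121Gly	likely_pathogenic
S031	MYH6	128	p.Arg128Leu	pathogenic
S032	MYH7	135	p.Gln135Cys	likely_pathogenic
S033	PLN	142	p.Tyr142Gly	pathogenic
S034	RBM20	149	p.Trp149Arg	likely_pathogenic
S035	TNNI3	156	p.Gly156Ser	pathogenic
S036	KCNQ1	311	p.Trp311Cys	pathogenic
S037	KCNH2	322	p.Gln322Gln	pathogenic
S038	SCN5A	333	p.Gly333Cys	pathogenic
S039	MYH11	344	p.Ser344Trp	pathogenic
S040	FBN1	355	p.Leu355Ser	pathogenic
S041	LDLR	366	p.Lys366Ser	pathogenic
S042	PKP2	377	p.Cys377Leu	pathogenic
S043	DSG2	388	p.Arg388Tyr	pathogenic
S044	RYR2	399	p.Arg399Gly	pathogenic
S045	.	.	.	.
S046	.	.	.	.
S047	.	.	.	.
S048	.	.	.	.
S049	.	.	.	.
S050	TTN	5000	p.Ala5000Val	vus
S051	TTN	21000	p.Arg21000Ter	vus
S052	MYH7	400	p.Val400Met	benign
S053	.	.	.	.
S054	.	.	.	.
S055	.	.	.	.
S056	.	.	.	.
S057	.	.	.	.
S058	.	.	.	.
S059	.	.	.	.
S060	.	.	.	.
S061	.	.	.	.
S062	.	.	.	.
S063	.	.	.	.
S064	.	.	.	.
S065	.	.	.	.
S066	.	.	.	.
S067	.	.	.	.
S068	.	.	.	.
S069	.	.	.	.
S070	.	.	.	.
S071	.	.	.	.
S072	.	.	.	.
S073	.	.	.	.
S074	.	.	.	.
S075	.	.	.	.
S076	.	.	.	.
S077	.	.	.	.
S078	.	.	.	.
S079	.	.	.	.
S080	.	.	.	.
S081	.	.	.	.
S082	.	.	.	.
S083	.	.	.	.
S084	.	.	.	.
S085	.	.	.	.
S086	.	.	.	.
S087	.	.	.	.
S088	.	.	.	.
S089	.	.	.	.
S090	.	.	.	.
S091	.	.	.	.
S092	.	.	.	.
S093	.	.	.	.
S094	.	.	.	.
S095	.	.	.	.
S096	.	.	.	.
S097	.	.	.	.
S098	.	.	.	.
S099	.	.	.	.
S100	.	.	.	.
S101	.	.	.	.
S102	.	.	.	.
S103	.	.	.	.
S104	.	.	.	.
S105	.	.	.	.
S106	.	.	.	.
S107	.	.	.	.
S108	.	.	.	.
S109	.	.	.	.
S110	.	.	.	.
S111	.	.	.	.
S112	.	.	.	.
S113	.	.	.	.
S114	.	.	.	.
S115	.	.	.	.
S116	.	.	.	.
S117	.	.	.	.
S118	.	.	.	.
S119	.	.	.	.
S120	.	.	.	.
S121	.	.	.	.
S122	.	.	.	.
S123	.	.	.	.
S124	.	.	.	.
S125	.	.	.	.
S126	.	.	.	.
S127	.	.	.	.
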