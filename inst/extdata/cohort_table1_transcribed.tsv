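# Clinical cohort transcribed from the published study tables.
# Rows with cna_positive=TRUE: one per CNA-detected patient; cancer type,
# FIGO stage and total CNA size (Mb) transcribed from the per-sample table.
# Rows with cna_positive=FALSE: counts per (type, stage group) from the
# cohort summary table; the individual stage label within the group is a
# synthetic placeholder (only the I-II / III-IV grouping is published).
# Per-patient survival times were not published: pfs/os columns are NA.
sample_id	cancer_type	figo_stage	pfs_months	pfs_event	os_months	os_event	cna_positive	total_cna_mb
T2_01	ovarian	IIIB	NA	NA	NA	NA	TRUE	31
T2_02	ovarian	IIIB	NA	NA	NA	NA	TRUE	565
T2_03	ovarian	IIIB	NA	NA	NA	NA	TRUE	771
T2_04	ovarian	IIIC	NA	NA	NA	NA	TRUE	981
T2_05	ovarian	IIIB	NA	NA	NA	NA	TRUE	1767
T2_06	ovarian	IA	NA	NA	NA	NA	TRUE	2448
T2_07	cervical	IIB	NA	NA	NA	NA	TRUE	21
T2_08	cervical	IB	NA	NA	NA	NA	TRUE	89
T2_09	cervical	IB	NA	NA	NA	NA	TRUE	1077
T2_10	endometrial	IIIA	NA	NA	NA	NA	TRUE	62
T2_11	endometrial	IIIC	NA	NA	NA	NA	TRUE	79
T2_12	endometrial	IA	NA	NA	NA	NA	TRUE	93
T2_13	endometrial	IA	NA	NA	NA	NA	TRUE	97
T2_14	endometrial	IIIC	NA	NA	NA	NA	TRUE	102
T2_15	endometrial	IA	NA	NA	NA	NA	TRUE	248
T2_16	endometrial	II	NA	NA	NA	NA	TRUE	248
T2_17	endometrial	IIIA	NA	NA	NA	NA	TRUE	821
T2_18	endometrial	IV	NA	NA	NA	NA	TRUE	834
T2_19	endometrial	IB	NA	NA	NA	NA	TRUE	1491
N_001	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_002	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_003	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_004	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_005	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_006	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_007	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_008	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_009	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_010	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_011	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_012	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_013	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_014	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_015	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_016	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_017	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_018	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_019	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_020	ovarian	I	NA	NA	NA	NA	FALSE	NA
N_021	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_022	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_023	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_024	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_025	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_026	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_027	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_028	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_029	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_030	ovarian	III	NA	NA	NA	NA	FALSE	NA
N_031	cervical	I	NA	NA	NA	NA	FALSE	NA
N_032	cervical	I	NA	NA	NA	NA	FALSE	NA
N_033	cervical	I	NA	NA	NA	NA	FALSE	NA
N_034	cervical	I	NA	NA	NA	NA	FALSE	NA
N_035	cervical	I	NA	NA	NA	NA	FALSE	NA
N_036	cervical	I	NA	NA	NA	NA	FALSE	NA
N_037	cervical	I	NA	NA	NA	NA	FALSE	NA
N_038	cervical	I	NA	NA	NA	NA	FALSE	NA
N_039	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_040	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_041	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_042	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_043	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_044	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_045	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_046	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_047	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_048	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_049	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_050	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_051	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_052	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_053	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_054	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_055	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_056	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_057	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_058	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_059	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_060	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_061	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_062	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_063	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_064	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_065	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_066	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_067	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_068	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_069	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_070	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_071	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_072	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_073	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_074	endometrial	I	NA	NA	NA	NA	FALSE	NA
N_075	endometrial	III	NA	NA	NA	NA	FALSE	NA
N_076	endometrial	III	NA	NA	NA	NA	FALSE	NA
N_077	endometrial	III	NA	NA	NA	NA	FALSE	NA
N_078	endometrial	III	NA	NA	NA	NA	FALSE	NA
N_079	endometrial	III	NA	NA	NA	NA	FALSE	NA
N_080	endometrial	III	NA	NA	NA	NA	FALSE	NA
N_081	endometrial	III	NA	NA	NA	NA	FALSE	NA
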