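subject_id	status	age	sex	country	subtype	jak2
S00001	case	46.6	female	Spain	ET	negative
S00002	case	51.7	female	Poland	PMF	positive
S00003	case	45.8	female	Spain	PV	negative
S00004	case	52.9	female	Spain	ET	negative
S00005	case	24.7	male	Spain	PV	positive
S00006	case	57.7	female	Hungary	ET	negative
S00007	case	52.4	female	Italy	CML	positive
S00008	case	61.6	female	Spain	PV	positive
S00009	case	58.5	female	Italy	ET	positive
S00010	case	51.7	male	Poland	CML	positive
S00011	case	66.3	male	Hungary	ET	negative
S00012	case	49.4	male	Poland	ET	negative
S00013	case	59.3	female	Spain	ET	negative
S00014	case	31.7	female	Spain	PV	positive
S00015	case	53.4	female	Spain	ET	negative
S00016	case	50.1	female	Poland	PV	positive
S00017	case	67.7	male	Poland	ET	positive
S00018	case	53.6	male	Spain	CML	positive
S00019	case	60.9	male	Spain	PV	negative
S00020	case	61.9	male	Spain	CML	negative
S00021	case	52	male	Poland	ET	negative
S00022	case	61.5	female	Spain	PMF	negative
S00023	case	73.8	male	Spain	ET	negative
S00024	case	53.6	female	Spain	ET	negative
S00025	case	44.5	female	Hungary	CML	positive
S00026	case	60.4	female	Spain	PV	positive
S00027	case	47.7	male	Poland	PMF	positive
S00028	case	64.5	female	Spain	ET	positive
S00029	case	32.8	male	Poland	CML	positive
S00030	case	84	male	Spain	CML	negative
S00031	case	44.1	female	Spain	PV	negative
S00032	case	49.6	female	Spain	ET	negative
S00033	case	54.4	male	Spain	CML	negative
S00034	case	50.4	male	Italy	CML	positive
S00035	case	37	male	Italy	CML	negative
S00036	case	59.5	male	Spain	ET	positive
S00037	case	50.1	male	Spain	PMF	negative
S00038	case	48.9	male	Italy	CML	negative
S00039	case	38.9	female	Poland	PV	positive
S00040	case	49.9	female	Spain	ET	negative
S00041	control	45.2	female	Spain	none	unknown
S00042	control	48.6	male	Hungary	none	unknown
S00043	control	35.6	male	Hungary	none	unknown
S00044	control	50	female	Poland	none	unknown
S00045	control	43.8	female	Italy	none	unknown
S00046	control	56.2	male	Poland	none	unknown
S00047	control	67.3	male	Spain	none	unknown
S00048	control	81.4	female	Spain	none	unknown
S00049	control	56.4	female	Italy	none	unknown
S00050	control	44.7	female	Spain	none	unknown
S00051	control	76.3	male	Italy	none	unknown
S00052	control	47.5	male	Italy	none	unknown
S00053	control	62.6	male	Spain	none	unknown
S00054	control	47.8	female	Spain	none	unknown
S00055	control	58	male	Spain	none	unknown
S00056	control	56.1	female	Spain	none	unknown
S00057	control	39.6	female	Spain	none	unknown
S00058	control	48	male	Poland	none	unknown
S00059	control	61.6	female	Spain	none	unknown
S00060	control	40.1	male	Poland	none	unknown
S00061	control	37.1	female	Hungary	none	unknown
S00062	control	39.3	male	Italy	none	unknown
S00063	control	37.2	female	Spain	none	unknown
S00064	control	39.8	male	Spain	none	unknown
S00065	control	47	male	Spain	none	unknown
S00066	control	29.9	female	Spain	none	unknown
S00067	control	43.3	male	Spain	none	unknown
S00068	control	58.7	male	Hungary	none	unknown
S00069	control	46.6	female	Spain	none	unknown
S00070	control	51.6	male	Spain	none	unknown
S00071	control	57.1	male	Hungary	none	unknown
S00072	control	50.1	female	Spain	none	unknown
S00073	control	30.1	male	Spain	none	unknown
S00074	control	62.1	male	Spain	none	unknown
S00075	control	38.7	female	Poland	none	unknown
S00076	control	45.4	male	Spain	none	unknown
S00077	control	42.9	male	Spain	none	unknown
S00078	control	56.2	male	Hungary	none	unknown
S00079	control	46.9	male	Spain	none	unknown
S00080	control	75.4	female	Spain	none	unknown
S00081	control	59.8	female	Italy	none	unknown
S00082	control	43.6	male	Hungary	none	unknown
S00083	control	48.4	female	Hungary	none	unknown
S00084	control	50.2	male	Italy	none	unknown
S00085	control	57.2	female	Poland	none	unknown
S00086	control	29.6	female	Spain	none	unknown
S00087	control	46.3	male	Spain	none	unknown
S00088	control	51.2	male	Spain	none	unknown
S00089	control	68.5	female	Spain	none	unknown
S00090	control	44.1	male	Poland	none	unknown
S00091	control	53.4	female	Spain	none	unknown
S00092	control	41.1	male	Spain	none	unknown
S00093	control	59.6	male	Spain	none	unknown
S00094	control	53.4	male	Spain	none	unknown
S00095	control	62.1	male	Spain	none	unknown
S00096	control	37.7	male	Spain	none	unknown
S00097	control	46.1	male	Spain	none	unknown
S00098	control	40.6	female	Spain	none	unknown
S00099	control	49.2	male	Spain	none	unknown
S00100	control	52.3	male	Spain	none	unknown
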