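subject_id	rs412658	rs8105767	rs3027234	rs9420907	rs755017	rs6028466	rs7675998	rs10936599	rs11125529	rs6772228	rs2736100
S00001	NA	1	1	1	0	0	2	2	0	2	NA
S00002	2	0	2	0	0	0	2	1	1	2	1
S00003	1	1	2	0	0	1	2	NA	0	2	2
S00004	2	NA	2	1	0	1	1	1	2	2	1
S00005	1	0	1	1	0	0	2	1	0	2	2
S00006	1	0	2	0	0	0	2	2	0	2	0
S00007	0	0	1	1	NA	0	1	2	1	2	0
S00008	0	NA	2	0	1	0	1	2	1	2	1
S00009	2	NA	2	0	0	0	2	2	0	2	1
S00010	0	0	2	1	0	0	1	NA	0	2	0
S00011	2	0	2	0	0	0	1	2	0	1	2
S00012	1	1	2	1	0	0	2	2	0	2	1
S00013	NA	0	0	0	0	0	1	1	1	2	1
S00014	1	0	1	1	0	0	2	0	0	2	0
S00015	1	1	2	1	1	1	NA	1	0	2	1
S00016	0	0	2	1	0	0	2	1	0	2	0
S00017	2	2	1	0	0	0	2	2	0	2	0
S00018	0	0	2	0	0	0	2	1	0	2	2
S00019	0	0	2	0	0	0	1	1	1	2	2
S00020	0	0	2	1	1	0	2	2	0	1	2
S00021	1	0	1	0	0	0	1	2	0	1	1
S00022	1	2	2	1	0	0	2	2	0	1	2
S00023	0	0	1	NA	0	0	2	2	0	1	1
S00024	NA	1	1	0	0	0	2	2	1	2	2
S00025	2	0	1	0	0	0	2	0	0	2	1
S00026	1	1	1	0	1	1	2	2	0	2	1
S00027	0	0	1	0	1	0	NA	1	1	2	1
S00028	1	2	2	0	0	0	1	2	0	2	0
S00029	0	1	1	1	0	0	2	1	0	2	1
S00030	0	0	2	0	1	0	2	2	1	2	2
S00031	1	1	2	1	0	0	2	2	0	2	2
S00032	1	0	2	0	0	1	2	1	0	2	2
S00033	2	0	0	0	1	0	2	2	0	2	2
S00034	NA	0	1	0	0	0	2	1	0	NA	1
S00035	0	0	1	0	0	1	2	1	0	2	NA
S00036	0	1	2	1	0	0	0	2	0	2	1
S00037	0	0	2	2	0	NA	1	2	0	NA	1
S00038	1	0	2	0	0	1	2	2	0	2	1
S00039	0	1	1	0	0	NA	2	NA	2	2	2
S00040	2	0	1	0	0	0	2	2	0	2	1
S00041	0	0	2	1	0	0	2	2	0	2	2
S00042	2	1	2	0	0	0	2	1	0	2	1
S00043	1	2	2	0	0	0	1	1	0	2	1
S00044	1	0	2	0	0	0	0	2	1	1	0
S00045	0	0	2	0	0	0	2	2	0	2	0
S00046	1	1	2	0	0	1	2	NA	0	2	1
S00047	0	1	1	1	0	0	2	2	0	1	0
S00048	0	1	1	0	NA	0	2	2	0	2	1
S00049	0	1	2	0	0	0	2	2	0	2	0
S00050	1	0	2	0	0	0	2	1	0	2	1
S00051	1	1	2	0	0	0	1	2	0	2	0
S00052	1	1	2	0	0	0	1	1	0	2	1
S00053	1	0	1	0	0	0	2	1	0	2	1
S00054	0	1	2	0	0	0	1	2	0	2	2
S00055	0	0	1	0	0	0	1	2	1	2	1
S00056	0	1	2	NA	1	1	2	2	1	2	2
S00057	1	1	1	1	0	0	1	1	0	2	2
S00058	0	0	0	0	0	0	1	2	0	2	2
S00059	1	1	2	NA	0	1	1	2	0	2	NA
S00060	0	1	2	0	1	0	2	1	0	2	2
S00061	0	0	1	1	0	0	2	2	1	2	1
S00062	1	1	1	1	0	0	0	2	1	2	1
S00063	1	1	1	0	0	NA	1	1	0	2	0
S00064	1	NA	NA	1	1	1	1	2	0	2	1
S00065	1	1	1	0	1	0	1	2	0	2	0
S00066	0	1	2	0	0	0	2	1	0	2	0
S00067	1	0	1	0	0	0	2	1	0	2	2
S00068	1	0	2	0	0	NA	1	2	0	2	0
S00069	0	1	2	0	1	0	2	2	0	2	0
S00070	1	0	2	0	0	0	2	2	0	2	1
S00071	0	0	2	0	1	0	1	2	0	2	1
S00072	1	0	2	0	0	0	2	2	1	2	1
S00073	0	1	2	0	0	0	2	2	1	2	0
S00074	0	0	2	1	1	0	2	NA	1	2	0
S00075	1	1	2	0	0	0	0	2	0	2	1
S00076	0	0	2	0	0	1	0	2	0	2	1
S00077	2	0	1	0	0	0	2	2	0	2	1
S00078	0	0	2	0	0	NA	2	2	0	2	1
S00079	0	0	2	1	0	0	1	2	0	2	0
S00080	1	1	0	0	0	0	2	2	1	2	2
S00081	0	1	0	1	0	0	2	0	1	2	0
S00082	1	NA	1	1	0	0	1	1	0	2	1
S00083	0	0	2	0	0	1	2	0	0	2	0
S00084	0	NA	0	1	1	0	1	1	0	NA	0
S00085	1	0	2	0	0	1	1	1	0	2	1
S00086	1	1	2	0	0	0	1	2	0	2	2
S00087	1	0	1	0	1	0	2	0	0	NA	NA
S00088	0	0	1	0	1	0	2	2	0	2	1
S00089	NA	1	2	NA	0	1	2	1	0	2	2
S00090	0	1	2	0	0	0	2	1	0	2	1
S00091	0	0	2	0	0	0	2	2	0	2	2
S00092	0	1	1	0	1	0	2	1	0	2	1
S00093	1	1	2	0	0	0	1	2	0	2	1
S00094	2	1	2	1	1	0	1	0	0	2	0
S00095	0	0	2	1	0	0	2	2	0	2	1
S00096	1	1	2	0	0	0	2	1	1	2	1
S00097	0	1	2	1	1	0	2	2	1	1	2
S00098	0	0	NA	0	1	0	0	2	1	2	1
S00099	1	1	2	0	0	0	1	0	0	2	0
S00100	0	1	2	0	1	NA	2	2	0	2	1
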