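TOY_SET_1	synthetic toy gene set 1	EG0042	EG0083	EG0031	EG0092	EG0103	EG0066	EG0015	EG0090	EG0008	EG0067	EG0088	EG0040
TOY_SET_2	synthetic toy gene set 2	EG0022	EG0047	EG0008	EG0059	EG0090	EG0012	EG0051	EG0020	EG0040	EG0031	EG0079	EG0006
TOY_SET_3	synthetic toy gene set 3	EG0016	EG0022	EG0059	EG0021	EG0004	EG0011	EG0102	EG0026	EG0087	EG0002	EG0100	EG0038
TOY_SET_4	synthetic toy gene set 4	EG0120	EG0043	EG0072	EG0081	EG0078	EG0036	EG0003	EG0109	EG0053	EG0088	EG0041	EG0112
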