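TCELL_ACTIVATION_SIM	synthetic T-cell activation module	IMM001	IMM002	IMM003	IMM004	IMM005	IMM006	IMM007	IMM008	IMM009	IMM010	IMM011	IMM012	IMM013	IMM014	IMM015	IMM016	IMM017	IMM018	IMM019	IMM020	IMM021	IMM022	IMM023	IMM024	IMM025	IMM026	IMM027	IMM028	IMM029	IMM030
RANDOM_CONTROL_SIM	synthetic control gene set	SIMG00002	SIMG00004	SIMG00006	SIMG00008	SIMG00010	SIMG00012	SIMG00014	SIMG00016	SIMG00018	SIMG00020	SIMG00022	SIMG00024	SIMG00026	SIMG00028	SIMG00030
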