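g001	GO:0000003
g002	GO:0000003
g003	GO:0000003
g004	GO:0000003
g005	GO:0000003
g006	GO:0000003
g007	GO:0000003
g008	GO:0000003
g009	GO:0000002
g010	GO:0000002
g011	GO:0000002
g012	GO:0000002
g013	GO:0000002
g014	GO:0000002
g015	GO:0000001
g016	GO:0000001
g017	GO:0000001
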