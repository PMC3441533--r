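g001	g013
g002	g014
g003	g015
g004	g016
g005	g017
g030	g040
g031	g041
g032	g042
g050	g060
g051	g052
g061	g062
g020	g045
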