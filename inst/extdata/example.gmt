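GLYCOLYSIS	toy glycolysis pathway	g001	g002	g003	g004	g005	g006	g007	g008	g009	g010	g011	g012
TCA_CYCLE	toy citrate cycle	g009	g010	g011	g012	g013	g014	g015	g016	g017	g018	g019	g020
DNA_REPAIR	toy repair machinery	g030	g031	g032	g033	g034	g035	g036	g037	g038	g039
CELL_CYCLE	toy cell cycle	g036	g037	g038	g039	g040	g041	g042	g043	g044	g045
RIBOSOME	toy ribosome components	g050	g051	g052	g053	g054	g055	g056	g057	g058	g059
SIGNALING	toy signaling cascade	g060	g061	g062	g063	g064	g065	g066	g067	g068	g069
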