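id	name	assigned_subpop
acc001	acc001	UNASSIGNED
acc002	acc002	UNASSIGNED
acc003	acc003	UNASSIGNED
acc004	acc004	UNASSIGNED
acc005	acc005	UNASSIGNED
acc006	acc006	UNASSIGNED
acc007	acc007	UNASSIGNED
acc008	acc008	UNASSIGNED
acc009	acc009	UNASSIGNED
acc010	acc010	UNASSIGNED
acc011	acc011	UNASSIGNED
acc012	acc012	UNASSIGNED
acc013	acc013	UNASSIGNED
acc014	acc014	UNASSIGNED
acc015	acc015	UNASSIGNED
acc016	acc016	UNASSIGNED
acc017	acc017	UNASSIGNED
acc018	acc018	UNASSIGNED
acc019	acc019	UNASSIGNED
acc020	acc020	UNASSIGNED
acc021	acc021	UNASSIGNED
acc022	acc022	UNASSIGNED
acc023	acc023	UNASSIGNED
acc024	acc024	UNASSIGNED
acc025	acc025	UNASSIGNED
acc026	acc026	UNASSIGNED
acc027	acc027	UNASSIGNED
acc028	acc028	UNASSIGNED
acc029	acc029	UNASSIGNED
acc030	acc030	UNASSIGNED
acc031	acc031	UNASSIGNED
acc032	acc032	UNASSIGNED
acc033	acc033	UNASSIGNED
acc034	acc034	UNASSIGNED
acc035	acc035	UNASSIGNED
acc036	acc036	UNASSIGNED
acc037	acc037	UNASSIGNED
acc038	acc038	UNASSIGNED
acc039	acc039	UNASSIGNED
acc040	acc040	UNASSIGNED
acc041	acc041	UNASSIGNED
acc042	acc042	UNASSIGNED
acc043	acc043	UNASSIGNED
acc044	acc044	UNASSIGNED
acc045	acc045	UNASSIGNED
acc046	acc046	UNASSIGNED
acc047	acc047	UNASSIGNED
acc048	acc048	UNASSIGNED
acc049	acc049	UNASSIGNED
acc050	acc050	UNASSIGNED
acc051	acc051	UNASSIGNED
acc052	acc052	UNASSIGNED
acc053	acc053	UNASSIGNED
acc054	acc054	UNASSIGNED
acc055	acc055	UNASSIGNED
acc056	acc056	UNASSIGNED
acc057	acc057	UNASSIGNED
acc058	acc058	UNASSIGNED
acc059	acc059	UNASSIGNED
acc060	acc060	UNASSIGNED
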