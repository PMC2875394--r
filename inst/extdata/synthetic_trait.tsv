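id	value
acc001	2.20030767073373
acc002	0.848718250909349
acc003	-0.667902079960952
acc004	1.6033785249321
acc005	-0.933777527125746
acc006	-0.911273326751468
acc007	0.719702162950415
acc008	1.88749030493885
acc009	0.146855028080104
acc010	2.10673586560345
acc011	2.34341699236339
acc012	2.61348659162774
acc013	2.1947327153848
acc014	2.31170434572721
acc015	3.82399654127557
acc016	2.44990372440148
acc017	-0.85982687850824
acc018	-0.295646586138474
acc019	-0.00463911941227789
acc020	0.950603500504289
acc021	0.807830998333969
acc022	0.678531409837299
acc023	3.25632430175384
acc024	-1.33523773641005
acc025	1.22453261193933
acc026	0.177191505270568
acc027	2.72368533366785
acc028	0.569252505832983
acc029	-0.945686239672483
acc030	-0.265570616203119
acc031	-0.837749508409472
acc032	0.691391979720162
acc033	0.106446902573458
acc034	-0.0754842040615479
acc035	-0.404507391592212
acc036	-0.540759170418421
acc037	2.95959742403561
acc038	-1.06312347290885
acc039	-0.136879394058092
acc040	2.30302177971038
acc041	1.17223277552645
acc042	1.32726433832143
acc043	-0.274583299646202
acc044	-1.26169985250847
acc045	1.62385016065959
acc046	-0.386264371305987
acc047	1.29918368377117
acc048	2.56871857727143
acc049	0.0967044291767351
acc050	0.895681449899602
acc051	1.74724462893695
acc052	1.9926233640577
acc053	2.35319732396644
acc054	3.64227238172812
acc055	2.69623050721231
acc056	2.46275161065284
acc057	-1.50827273185761
acc058	0.306153419618037
acc059	0.159682026662801
acc060	1.13429834174013
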