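exposure	mediator	outcome	beta_total	se_total	or_xm	lci_xm	uci_xm	or_my	lci_my	uci_my	proportion	se_proportion	prop_lci	prop_uci
cognitive performance	income	Psoriasis	-0.373941102	0.069055281	1.50769	1.466478	1.550061	0.549813	0.410833	0.735808	0.656785	0.204617	0.255736	1.057835
cognitive performance	income	Autoimmune	-0.172682878	0.028304843	1.50769	1.466478	1.550061	0.78188	0.68441	0.893232	0.585029	0.188915	0.214756	0.955302
cognitive performance	income	Hypothyroidism	-0.182584505	0.041299132	1.50769	1.466478	1.550061	0.767283	0.635874	0.925849	0.595681	0.255003	0.095874	1.095487
educational attainment	income	Psoriasis	-0.494513057	0.081186747	1.905603	1.848091	1.964905	0.549813	0.410833	0.735808	0.779967	0.233094	0.323103	1.236831
educational attainment	income	Autoimmune	-0.20212243	0.033402482	1.905603	1.848091	1.964905	0.78188	0.68441	0.893232	0.784945	0.253283	0.288512	1.281379
educational attainment	income	Hypothyroidism	-0.226873575	0.049699192	1.905603	1.848091	1.964905	0.767283	0.635874	0.925849	0.752872	0.31896	0.127711	1.378033
highest-level math class completed	income	Psoriasis	-0.413976226	0.069417995	1.635315	1.590684	1.681199	0.549813	0.410833	0.735808	0.710681	0.214047	0.291149	1.130213
highest-level math class completed	income	Autoimmune	-0.154453283	0.029044706	1.635315	1.590684	1.681199	0.78188	0.68441	0.893232	0.783525	0.262694	0.268645	1.298405
highest-level math class completed	income	Hypothyroidism	-0.159461896	0.040686424	1.635315	1.590684	1.681199	0.767283	0.635874	0.925849	0.817041	0.362489	0.106563	1.527519
self-reported math ability	income	Psoriasis	-0.275794282	0.078016505	1.430427	1.382775	1.479722	0.549813	0.410833	0.735808	0.776418	0.294756	0.198697	1.354139
self-reported math ability	income	Autoimmune	-0.140528496	0.032171725	1.430427	1.382775	1.479722	0.78188	0.68441	0.893232	0.626781	0.226825	0.182204	1.071359
self-reported math ability	income	Hypothyroidism	NA	NA	1.430427	1.382775	1.479722	0.767283	0.635874	0.925849	0.667055	0.329806	0.020635	1.313476
cognitive performance	smoking	Asthma	NA	NA	0.807208	0.764956	0.851795	1.13379	1.034161	1.243018	0.375113	0.221763	-0.05954	0.809769
cognitive performance	smoking	Rheumatoid arthritis	-0.284183799	0.062031243	0.807208	0.764956	0.851795	1.223039	1.046519	1.429333	0.151738	0.071181	0.012223	0.291252
cognitive performance	smoking	Primary sclerosing cholangitis	NA	NA	0.807208	0.764956	0.851795	0.626455	0.39393	0.996232	0.706859	0.840457	-0.94044	2.354155
educational attainment	smoking	Asthma	-0.177764568	0.039456558	0.630071	0.595589	0.666549	1.13379	1.034161	1.243018	0.326285	0.143267	0.045481	0.607088
educational attainment	smoking	Rheumatoid arthritis	-0.378116951	0.07208655	0.630071	0.595589	0.666549	1.223039	1.046519	1.429333	0.245963	0.108954	0.032413	0.459514
educational attainment	smoking	Primary sclerosing cholangitis	NA	NA	0.630071	0.595589	0.666549	0.626455	0.39393	0.996232	0.471151	0.304755	-0.12617	1.068472
highest-level math class completed	smoking	Asthma	NA	NA	0.695063	0.66241	0.729325	1.13379	1.034161	1.243018	0.439509	0.220147	0.008021	0.870998
highest-level math class completed	smoking	Rheumatoid arthritis	-0.336537501	0.061843631	0.695063	0.66241	0.729325	1.223039	1.046519	1.429333	0.217621	0.095935	0.029588	0.405653
highest-level math class completed	smoking	Primary sclerosing cholangitis	NA	NA	0.695063	0.66241	0.729325	0.626455	0.39393	0.996232	0.382288	0.240743	-0.08957	0.854144
self-reported math ability	smoking	Asthma	NA	NA	0.797476	0.75123	0.846569	1.13379	1.034161	1.243018	1.635822	3.469853	-5.16509	8.436733
self-reported math ability	smoking	Rheumatoid arthritis	-0.268734777	0.066417063	0.797476	0.75123	0.846569	1.223039	1.046519	1.429333	0.169548	0.082232	0.008373	0.330724
self-reported math ability	smoking	Primary sclerosing cholangitis	NA	NA	0.797476	0.75123	0.846569	0.626455	0.39393	0.996232	0.533246	0.544619	-0.53421	1.600699
educational attainment	BMI	Autoimmune	-0.20212243	0.033402482	0.865585	0.821038	0.912549	1.185114	1.13159	1.24117	0.121294	0.034619	0.053441	0.189147
educational attainment	BMI	Psoriasis	-0.494513057	0.081186747	0.865585	0.821038	0.912549	1.493734	1.334771	1.671628	0.117134	0.033603	0.051273	0.182995
educational attainment	BMI	Asthma	-0.177764568	0.039456558	0.865585	0.821038	0.912549	1.201392	1.138239	1.26805	0.148991	0.048665	0.053607	0.244376
educational attainment	BMI	Hypothyroidism	-0.226873575	0.049699192	0.865585	0.821038	0.912549	1.23817	1.154254	1.328188	0.135926	0.045277	0.047183	0.224669
educational attainment	BMI	Multiple sclerosis	NA	NA	0.865585	0.821038	0.912549	1.362429	1.196811	1.550965	0.46253	0.506158	-0.52954	1.4546
educational attainment	BMI	Rheumatoid arthritis	-0.378116951	0.07208655	0.865585	0.821038	0.912549	1.274386	1.149473	1.412873	0.092563	0.031843	0.030151	0.154975
educational attainment	BMI	Asthma and allergy	NA	NA	0.865585	0.821038	0.912549	1.286871	1.092069	1.516421	0.273891	0.260531	-0.23675	0.784532
educational attainment	BMI	Primary biliary cholangitis	NA	NA	0.865585	0.821038	0.912549	1.295683	1.089482	1.540911	0.118392	0.078001	-0.03449	0.271273
highest-level math class completed	BMI	Autoimmune	-0.154453283	0.029044706	0.91056	0.867076	0.956224	1.185114	1.13159	1.24117	0.103029	0.036519	0.031452	0.174606
highest-level math class completed	BMI	Psoriasis	-0.413976226	0.069417995	0.91056	0.867076	0.956224	1.493734	1.334771	1.671628	0.090822	0.031407	0.029264	0.15238
highest-level math class completed	BMI	Asthma	NA	NA	0.91056	0.867076	0.956224	1.201392	1.138239	1.26805	0.165425	0.074021	0.020345	0.310505
highest-level math class completed	BMI	Hypothyroidism	-0.159461896	0.040686424	0.91056	0.867076	0.956224	1.23817	1.154254	1.328188	0.125527	0.050864	0.025833	0.22522
highest-level math class completed	BMI	Multiple sclerosis	NA	NA	0.91056	0.867076	0.956224	1.362429	1.196811	1.550965	0.249999	0.216378	-0.1741	0.674099
highest-level math class completed	BMI	Rheumatoid arthritis	-0.336537501	0.061843631	0.91056	0.867076	0.956224	1.274386	1.149473	1.412873	0.067505	0.026309	0.01594	0.11907
highest-level math class completed	BMI	Asthma and allergy	NA	NA	0.91056	0.867076	0.956224	1.286871	1.092069	1.516421	0.169121	0.138208	-0.10177	0.440008
highest-level math class completed	BMI	Primary biliary cholangitis	-0.633260865	0.167368488	0.91056	0.867076	0.956224	1.295683	1.089482	1.540911	0.038327	0.019445	0.000214	0.076439
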