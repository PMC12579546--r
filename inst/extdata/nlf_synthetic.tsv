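residue	F1	F2	F3	F4	F5	F6	F7	F8	F9	F10	F11	F12	F13	F14	F15	F16	F17	F18
A	0.07672	0.81262	-0.91612	-0.52562	0.00358	0.24018	0.18953	0.65578	-0.04659	1.35723	-0.33298	-0.04468	-0.37115	-0.1267	0.51917	0.23245	-0.29981	0.63579
C	-1.08428	1.33168	-1.11198	-1.56185	0.81414	1.82799	-1.04824	-0.74159	0.37866	-0.12063	0.10241	-0.07204	0.19693	0.05611	-0.12476	-0.18225	-0.00756	-0.0267
D	1.55058	1.23014	0.00457	-0.32308	0.49336	-0.99123	0.00981	-1.61519	0.52627	-0.15048	0.28174	0.09681	-0.34121	0.1601	-0.08455	0.75098	0.14935	0.18556
E	1.47732	0.94209	0.22913	0.6699	-0.35481	-0.2839	-0.07487	-1.01445	0.36258	0.76919	-0.29758	0.21482	-0.1343	-0.21154	0.08375	-0.84136	-0.05148	0.10083
F	-1.61862	1.15089	1.00655	0.31133	0.62251	-0.54921	0.28975	-0.0208	0.09789	0.43316	1.2878	-0.44405	-0.4613	0.17641	-0.25591	-0.46818	-0.336	-0.07266
G	0.8487	1.47261	0.17395	-1.72589	0.09272	-0.54811	1.18599	1.21257	0.87398	0.00887	-0.24202	0.00698	0.21688	0.27697	-0.39836	-0.14812	0.30986	-0.11412
H	0.71613	0.93482	1.54762	0.80227	1.5467	0.35038	-0.78545	0.65526	-0.07601	-0.18554	-0.99009	0.18837	-0.64985	-0.36981	-0.31514	0.00872	0.09909	-0.07279
I	-1.46177	1.2498	-1.1258	0.76133	0.38221	-0.59878	0.276	-0.13172	0.19824	-0.21608	-0.20684	0.53893	0.05628	-0.12936	0.29522	0.18163	-0.21986	-0.54554
K	1.13511	0.93987	-0.03941	0.80196	-0.84863	0.81945	0.09711	0.21271	0.12883	0.17581	0.84987	0.43957	0.49845	-0.93658	-0.4958	0.14134	0.23835	0.08999
L	-1.40565	1.18845	-0.85591	0.87886	-0.1716	0.03246	0.34442	0.10924	0.14611	-0.43552	0.02064	-0.18536	-0.34512	-0.09083	0.56515	-0.2086	0.99617	0.16899
M	-0.96289	0.7071	-0.58488	0.9724	-0.52835	0.23595	0.3649	0.06234	0.20754	-0.56035	-0.36093	-1.19619	-0.21089	-0.0811	-0.61555	0.26551	-0.30081	0.38242
N	1.51106	0.96689	0.2147	0.04556	1.00936	0.11959	0.83374	-0.03311	-0.57	-1.2	0.13939	-0.19334	0.61783	-0.14278	0.53153	-0.28809	-0.40037	0.33808
P	0.88285	1.41516	-0.67538	-0.38194	-0.86861	-1.24326	-2.02323	0.84467	-0.35168	-0.42128	0.29754	-0.30611	0.03184	0.00828	0.11968	-0.08164	-0.08663	-0.0219
Q	1.09381	0.75914	0.29558	0.87057	-0.71794	0.49979	-0.0804	-0.44222	0.20225	0.38361	-0.66739	-0.84337	0.51752	0.70087	0.06518	-0.08323	0.06908	-0.32174
R	1.01401	1.10837	0.18942	0.85968	-0.60887	1.27677	0.19508	0.66134	0.17474	-0.21854	0.52035	0.6488	-0.51297	0.74721	0.25435	0.26241	-0.30757	-0.16882
S	0.84402	0.66438	-0.44767	-0.42326	0.31656	0.20024	0.54116	0.00881	-0.79748	0.62443	0.12862	-0.88002	-0.1379	-0.63958	0.22699	0.2803	-0.00909	-0.67138
T	0.18826	0.77522	-0.73316	-0.17774	-0.01232	0.0219	0.37753	-0.30371	-1.95821	0.14923	-0.06308	0.37692	-0.19189	0.54244	-0.55313	-0.11404	0.2996	0.10868
V	-1.1267	1.05006	-1.22663	0.63255	0.06366	-0.59629	0.15807	0.01403	0.01597	0.25106	-0.60708	0.65949	0.57704	-0.05353	-0.32757	-0.00145	-0.38099	-0.00199
W	-1.57722	1.34443	2.28139	-1.16593	-1.61007	0.12193	0.23921	-0.5419	-0.39841	-0.34861	-0.49916	0.24618	-0.13676	-0.33044	0.20207	0.08801	-0.16024	-0.01368
Y	-1.14169	0.81487	1.73985	0.5821	0.74738	-0.11877	-0.47472	0.24124	-0.25146	0.71258	0.25074	-0.09187	0.95314	0.29892	0.17343	0.39708	0.27398	0.19526
X	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
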