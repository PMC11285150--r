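# Transcription of a published compilation of spotted-hyena population
# density estimates (32 census studies; density in hyenas per km2).
# A trailing '*' on the reference code marks long-term studies and studies
# in which individuals were identified (the robust control subset).
# lon/lat are SYNTHETIC approximate gazetteer coordinates for the named
# protected areas, added here so the interpolation chain can be exercised;
# the source compilation prints no coordinates.
locality	country	density	years	method	reference	lon	lat
Pendjari NP	Benin	0.02	2001 to 2009	Camera traps	CIT0118*	1.5	11.25
Chobe NP	Botswana	0.44	1986 to 1988	Direct observations, radio collars	CIT0027*	24.5	-18.5
Moremi GR	Botswana	0.14	2007 to 2010	Audio playback	CIT0028	23.1	-19.2
Benoue ecosystem	Cameroon	0.06	2015	Audio playback	CIT0008	13.9	8.3
Tigray (Wukro Dist.)	Ethiopia	0.52	2011	Audio playback, GPS collars	CIT0134	39.6	13.8
Tigray (Enderta Dist.)	Ethiopia	0.8	2012	Direct observations, road transects, calling stations	CIT0135	39.5	13.4
Mole NP	Ghana	0.12	2006 to 2009	Camera traps, patrol-based monitoring	CIT0019*	-1.8	9.6
Masai Mara NR	Kenya	0.86	1979 to 1983	Direct observations, identification of individuals	CIT0042*	35.1	-1.5
Aberdare NP	Kenya	1.34	1986 to 1987	Audio playback to bait stations	CIT0108	36.7	-0.4
Masai Mara	Kenya	0.94	1988 to 1992	Direct observations, identification of individuals	CIT0129*	35.2	-1.4
Amboseli NP	Kenya	1.65	2003 to 2005	Direct observations, identification of individuals	CIT0129*	37.25	-2.65
Namib-Naukluft NP	Namibia	0.005	1976 to 1977	Direct observations, identification of individuals	CIT0123*	15.8	-24.0
Namib-Naukluft NP	Namibia	0.009	1977 to 1979	Direct observations, identification of individuals	CIT0124*	15.9	-24.2
Etosha NP	Namibia	0.05	1986	Direct observations, counts at waterholes, radio collars	CIT0043	16.0	-18.9
Etosha NP	Namibia	0.02	2008	Audio playback	CIT0125	16.3	-18.8
Odzala-Kotoua	Republic of Congo	0.46	1975 to 1977	Audio playback to bait stations	CIT0132*	14.9	0.6
Odzala-Kotoua NP	Republic of Congo	0.16	2007	Camera traps, track surveys	CIT0052*	15.0	0.5
Timbavati GR	South Africa	0.48	1973 to 1975	Observations of foraging; examination of scats and regurgitations	CIT0009	31.3	-24.4
Kruger NP	South Africa	0.32	1974 to 1975	Counts of culled individuals, aerial surveys	CIT0117	31.5	-24.0
Hluhluwe NP	South Africa	0.46	1975 to 1977	Audio playback to bait stations	CIT0132	32.1	-28.1
Umfolozi GR	South Africa	0.36	1979 to 1981	Bait stations	CIT0131	31.9	-28.3
Kalahari Gemsbok NP	South Africa	0.009	1979 to 1984	Direct observations individually identified hyenas	CIT0086*	20.6	-25.8
Kruger NP	South Africa	0.13	1982 to 1984	Camera traps, examination tracks, direct observations	CIT0051	31.4	-23.5
Kruger NP	South Africa	0.19	1984 to 1989	Audio playback	CIT0085	31.6	-24.8
Mkuze GR	South Africa	0.13	1989	Radio collars	CIT0113*	32.2	-27.6
Hluhluwe-iMfolozi	South Africa	0.36	2003 to 2004	Audio playback	CIT0046	32.0	-28.2
Serengeti	Tanzania	0.17	1965 to 1967	Direct observations, identification of individuals	CIT0063*	34.8	-2.3
Ngorongoro	Tanzania	1.54	1965 to 1967	Direct observations, identification of individuals	CIT0063*	35.5	-3.2
Selous GR	Tanzania	0.31	1991 to 1996	Audio playback	CIT0029	37.4	-9.0
Ngorongoro	Tanzania	0.59	1996	Direct observations, identification of individuals	CIT0056	35.6	-3.1
Liuwa Plains NP	Zambia	0.33	1995 to 1999	Examination of scat	CIT0093	22.6	-14.6
Hwange NP	Zimbabwe	0.07	1999 to 2003	Radio collars, audio playback	CIT0103	26.5	-18.6
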