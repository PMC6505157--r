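lg	cluster	markers	bins	length_cM	max_gap_cM
I	cluster1	975	421	385.5	8.0
II	cluster1	701	305	249.2	9.6
III	cluster1	859	394	324.0	4.6
IV	cluster1	771	323	298.7	14.5
V	cluster1	761	311	273.2	8.9
VI	cluster1	648	292	241.0	8.4
VII	cluster1	682	331	314.0	8.4
VIII	cluster1	775	339	307.0	5.6
IX	cluster1	792	332	283.3	5.4
X	cluster1	648	289	231.6	7.0
XI	cluster1	677	253	200.6	3.7
XII	cluster1	784	334	281.6	9.3
I	cluster2	1159	553	439.9	21.1
II	cluster2	863	366	289.0	9.4
III	cluster2	1069	479	381.1	7.1
IV	cluster2	970	452	350.9	8.6
V	cluster2	1116	499	395.6	9.5
VI	cluster2	915	399	270.7	4.6
VII	cluster2	923	443	380.8	13.4
VIII	cluster2	943	454	367.26	9.8
IX	cluster2	786	364	295.6	5.9
X	cluster2	960	454	342.7	6.9
XI	cluster2	1025	411	269.2	4.0
XII	cluster2	919	437	360.7	11.1
I	cluster3	1967	1185	414.1	8.8
II	cluster3	1456	864	289.8	10.9
III	cluster3	1738	1075	346.4	5.2
IV	cluster3	1531	916	303.0	27.0
V	cluster3	1649	1032	342.6	15.1
VI	cluster3	1456	894	269.5	8.4
VII	cluster3	1625	1013	321.9	7.9
VIII	cluster3	1465	904	315.6	6.6
IX	cluster3	1589	911	285.1	7.4
X	cluster3	1564	917	272.7	7.1
XI	cluster3	1440	818	233.6	3.0
XII	cluster3	1526	950	312.3	14.3
I	consensus	2172	NA	414.1	NA
II	consensus	1608	NA	250.3	NA
III	consensus	1940	NA	342.5	NA
IV	consensus	1704	NA	303.0	NA
V	consensus	1865	NA	275.0	NA
VI	consensus	1622	NA	240.2	NA
VII	consensus	1769	NA	321.0	NA
VIII	consensus	1609	NA	305.9	NA
IX	consensus	1738	NA	285.0	NA
X	consensus	1709	NA	273.1	NA
XI	consensus	1608	NA	233.4	NA
XII	consensus	1712	NA	312.3	NA
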