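lg	cluster	observed_cM	estimated_cM	sd_cM	inflation_printed
I	cluster1	385.5	245.5	5.2	0.33
II	cluster1	249.2	168.8	4.7	0.26
III	cluster1	324.0	195.8	5.8	0.33
IV	cluster1	298.7	204.7	5.0	0.29
V	cluster1	273.2	195.7	4.6	0.25
VI	cluster1	241.0	161.8	4.7	0.27
VII	cluster1	314.0	223.6	5.3	0.27
VIII	cluster1	307.0	203.6	4.9	0.31
IX	cluster1	283.3	194.0	4.9	0.27
X	cluster1	231.6	164.4	3.6	0.23
XI	cluster1	200.6	141.8	4.7	0.23
XII	cluster1	281.6	194.4	4.9	0.26
I	cluster2	439.9	252.3	6.1	0.34
II	cluster2	289.0	192.9	4.4	0.26
III	cluster2	381.1	218.6	5.8	0.34
IV	cluster2	350.9	215.6	5.7	0.30
V	cluster2	395.6	218.4	9.0	0.36
VI	cluster2	270.7	170.0	4.7	0.25
VII	cluster2	380.8	248.7	6.3	0.30
VIII	cluster2	367.26	226.7	5.7	0.31
IX	cluster2	295.6	185.3	6.8	0.30
X	cluster2	342.7	193.6	4.5	0.33
XI	cluster2	269.2	147.0	4.8	0.30
XII	cluster2	360.7	209.6	9.1	0.35
I	cluster3	414.2	204.8	7.3	0.18
II	cluster3	289.8	166.4	2.8	0.14
III	cluster3	346.4	168.5	3.9	0.17
IV	cluster3	303.0	167.0	3.5	0.15
V	cluster3	342.6	180.0	5.1	0.16
VI	cluster3	269.5	142.2	2.9	0.14
VII	cluster3	321.9	175.9	3.7	0.14
VIII	cluster3	315.6	179.2	4.3	0.15
IX	cluster3	285.1	157.2	3.0	0.14
X	cluster3	272.7	141.5	2.7	0.14
XI	cluster3	233.6	119.6	3.0	0.14
XII	cluster3	312.3	168.7	3.1	0.15
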