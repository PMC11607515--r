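feature_id	S01	S02	S03	S04	S05	S06
K00001	5.0893	0.4326	0.3945	1.0702	1.7268	0.1854
K00002	1.7339	1.5475	1.8034	0.6054	0.2873	1.2406
K00003	0.2329	4.7398	0.3663	1.2208	0.6047	1.1184
K00004	0.437	1.1527	1.7278	0.5641	0.9538	1.2452
K00005	4.428	0.8959	0.6679	0.2492	0.9128	1.0195
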