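feature_id	S01	S02	S03	S04	S05	S06
sp001	0.6015	0.3014	0.1979	1.1013	1.1639	9.8699
sp002	1.5761	0.7674	0.7326	1.4419	1.3961	1.2215
sp003	0.2317	0.3647	6.1048	0.5205	5.1228	0.353
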