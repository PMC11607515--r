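feature_id	S01	S02	S03	S04	S05	S06
feat001	3.6558	0.7874	1.7279	0.6105	0.1331	15.099
feat002	0.5553	0.609	1.3831	0.8169	0.2063	5.3996
feat003	1.0658	1.1745	1.6907	0.406	0.3626	2.675
feat004	1.4381	0.7768	0.6938	1.709	0.276	0.5207
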