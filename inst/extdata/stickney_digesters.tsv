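digester_id	volume_mg	flow_mgd	ts_ad	vs_ad	srt_d
1	2.3	0.106	0.0257	0.515	24.2
6	2.3	0.106	0.0225	0.535	24.2
14	2.8	0.120	0.0265	0.529	25.2
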