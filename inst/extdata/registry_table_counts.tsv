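variable	category	count	printed_pct
stage	I	12651	37.3
stage	II	2662	7.8
stage	III	11514	34.0
stage	IV	5813	17.1
stage	unstaged_other	1257	3.7
grade	1	1462	4.3
grade	2	13573	40.0
grade	3	18202	53.7
grade	4	660	1.9
sex	male	22218	65.5
sex	female	11679	34.5
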