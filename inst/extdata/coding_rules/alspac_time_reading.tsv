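response	code
not_at_all	0
less_than_1_hour	0
1_to_2_hours	1
3_or_more_hours	1
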