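response	code
never	0
less_than_5_hours_per_week	0
5_to_10_hours_per_week	1
11_to_15_hours_per_week	1
over_15_hours_per_week	1
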