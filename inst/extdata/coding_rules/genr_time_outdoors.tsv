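response	code
more_than_7_hours_per_week	0
7_hours_per_week	1
less_than_7_hours_per_week	1
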