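quantity,case_n,control_n
anchor_carriers,30,178
anchor_homozygotes,4,16
second_DRB4*01:03:01-DRB1*04:01:01-DQA1*03:02//03:03:01-DQB1*03:01:01,5,6
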