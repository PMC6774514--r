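block,category,case_n,control_n
DRB345,DRB3*01:01:02,1,18
DRB1,DRB1*03:01:01,1,16
DQA1,DQA1*01:02:01,38,55
DQA1,DQA1*03:02//03:03:01,9,13
DQB1,DQB1*02:01:01,1,16
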