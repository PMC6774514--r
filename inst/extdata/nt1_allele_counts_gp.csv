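block,category,case_n,control_n
DRB345,DRB3*03:01:01,4,56
DRB345,DRB4*01:03:01,13,307
DRB345,DRB5*01:01:01,34,205
DRB1,DRB1*04:01:01,7,126
DRB1,DRB1*13:02:01,4,56
DRB1,DRB1*15:01:01,34,202
DQA1,DQA1*01:02:01,38,265
DQA1,DQA1*03:02//03:03:01,9,81
DQB1,DQB1*03:01:01,11,203
DQB1,DQB1*06:02:01,34,201
DQB1,DQB1*06:04:01,4,52
DPA1,DPA1*02:06,3,6
DPB1,DPB1*02:01:02,3,178
DPB1,DPB1*04:02:01,2,152
DPB1,DPB1*23:01:01,2,4
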