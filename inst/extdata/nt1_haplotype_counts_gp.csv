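block,category,case_n,control_n
dr_drb1,DRB5*01:01:01-DRB1*15:01:01,34,201
dr_drb1,DRB4*01:03:01-DRB1*04:01:01,7,123
dr_drb1,DRB3*03:01:01-DRB1*13:02:01,4,55
dq,DQA1*01:02:01-DQB1*06:02:01,34,200
dq,DQA1*03:02//03:03:01-DQB1*03:01:01,7,56
dq,DQA1*01:02:01-DQB1*06:04:01,4,52
extended,DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01,34,194
extended,DRB4*01:03:01-DRB1*04:01:01-DQA1*03:02//03:03:01-DQB1*03:01:01,5,39
extended,DRB3*03:01:01-DRB1*13:02:01-DQA1*01:02:01-DQB1*06:04:01,4,51
extended,DRB4*01:03:01-DRB1*07:01:01-DQA1*02:01//02:01:01-DQB1*02:02:01,3,41
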