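block,category,case_n,control_n
genotype,DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01 / DRB4*01:03:01-DRB1*04:01:01-DQA1*03:02//03:03:01-DQB1*03:01:01,5,6
genotype,DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01 / DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01,4,16
genotype,DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01 / DRB3*03:01:01-DRB1*13:02:01-DQA1*01:02:01-DQB1*06:04:01,3,10
genotype,DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01 / DRBX*null-DRB1*08:01:01-DQA1*04:01:01-DQB1*04:02:01,2,6
genotype,DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01 / DRB3*02:02:01-DRB1*12:01:01-DQA1*05:05:01-DQB1*03:01:01,2,7
genotype,DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01 / DRB4*01:03:01-DRB1*07:01:01-DQA1*02:01//02:01:01-DQB1*02:02:01,2,8
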