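cross_id,mother_id,father_id,offspring_id,sex
60-2013,F60,M13,JUV01,male
60-2013,F60,M13,JUV02,male
60-2013,F60,M13,JUV03,male
60-2013,F60,M13,JUV04,male
60-2013,F60,M13,JUV05,male
60-2013,F60,M13,JUV06,male
60-2013,F60,M13,JUV07,male
60-2013,F60,M13,JUV19,male
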