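file,md5
groupB_ventilation.csv,a5e58e7c8b92546390e4eaac30d86633
groupB_collagen.csv,de7e139ae3722f464e2655fa4f2094e9
groupB_diagnoses.csv,a7f63b230ab2f9a803d41ff15b46f25b
groupA_findings.csv,a402e89814accf58eaace3f0fd7d56e0
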