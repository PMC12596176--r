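protocol,label,laa950,laa856
force_ref,lung_sample_a,2.7,5.3
drive_admire3_2.40,lung_sample_a,1.4,4.9
drive_admire5_2.40,lung_sample_a,1.3,5.0
drive_admire3_3.43,lung_sample_a,1.5,5.1
drive_admire5_3.43,lung_sample_a,1.3,5.2
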