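protocol,group,scanner,ctdi_vol,published_effective_dose
force_standard,standard,SOMATOM Force Qr40 ADMIRE off,7.32,5.93
definition_asplus_standard,standard,SOMATOM Definition AS+ B35 SAFIRE off,7.44,6.02
force,low,SOMATOM Force Qr40 ADMIRE 5,2.22,1.80
definition_asplus,low,SOMATOM Definition AS+ Q30 SAFIRE 5,3.52,2.85
definition_flash,low,SOMATOM Definition Flash Q30 SAFIRE 5,3.50,2.84
definition_edge,low,SOMATOM Definition Edge Q30 ADMIRE 5,3.54,2.87
drive,low,SOMATOM Drive Q30 ADMIRE 5,3.43,2.78
discovery_ct750hd,low,Discovery CT750 HD Standard ASiR-V 100,4.23,3.43
revolution_apex,low,Revolution Apex Standard ASiR-V 100,3.23,2.62
revolution_ct,low,Revolution CT Standard ASiR-V 100,3.24,2.62
brilliance_ict,low,Brilliance iCT B Standard iDose 6,3.50,2.85
aquilion_precision,low,Aquilion Precision AiCE body standard,3.05,2.47
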