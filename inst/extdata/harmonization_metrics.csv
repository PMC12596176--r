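protocol,scanner,recon,ctdi_vol,label,mean_hu,sd_hu
force_ref,SOMATOM Force,ADMIRE 5,2.22,air,-1002.3,15.4
force_ref,SOMATOM Force,ADMIRE 5,2.22,water_vial_1,3.8,26.2
force_ref,SOMATOM Force,ADMIRE 5,2.22,water_vial_2,3.4,24.6
force_ref,SOMATOM Force,ADMIRE 5,2.22,lung_sample_a,-655.6,131.5
force_ref,SOMATOM Force,ADMIRE 5,2.22,phantom_lung_foam,-629.2,33.3
force_ref,SOMATOM Force,ADMIRE 5,2.22,nist_4,-934.0,18.8
force_ref,SOMATOM Force,ADMIRE 5,2.22,nist_8,-883.1,17.4
force_ref,SOMATOM Force,ADMIRE 5,2.22,nist_12,-821.4,21.1
force_ref,SOMATOM Force,ADMIRE 5,2.22,nist_14,-778.1,21.1
force_ref,SOMATOM Force,ADMIRE 5,2.22,nist_20,-683.0,19.7
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,air,-984.9,23.4
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,water_vial_1,-3.2,37.2
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,water_vial_2,-7.3,35.7
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,lung_sample_a,-636.4,131.5
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,phantom_lung_foam,-614.4,40.6
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,nist_4,-902.2,34.5
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,nist_8,-857.7,33.5
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,nist_12,-758.4,32.4
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,nist_14,-800.0,33.0
drive_admire3_2.40,SOMATOM Drive,ADMIRE 3,2.40,nist_20,-662.3,35.5
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,air,-987.7,17.0
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,water_vial_1,-3.4,26.2
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,water_vial_2,-7.2,25.0
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,lung_sample_a,-636.5,128.4
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,phantom_lung_foam,-613.6,32.7
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,nist_4,-901.6,23.8
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,nist_8,-857.5,22.3
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,nist_12,-758.6,21.2
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,nist_14,-800.0,21.9
drive_admire5_2.40,SOMATOM Drive,ADMIRE 5,2.40,nist_20,-662.4,23.9
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,air,-987.6,21.7
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,water_vial_1,-0.9,32.7
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,water_vial_2,-1.6,30.0
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,lung_sample_a,-638.1,131.2
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,phantom_lung_foam,-614.1,38.0
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,nist_4,-901.6,27.0
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,nist_8,-861.1,24.6
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,nist_12,-758.9,24.2
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,nist_14,-804.1,26.1
drive_admire3_3.43,SOMATOM Drive,ADMIRE 3,3.43,nist_20,-664.5,29.7
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,air,-989.7,15.8
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,water_vial_1,-1.2,22.4
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,water_vial_2,-1.8,20.5
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,lung_sample_a,-638.3,128.5
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,phantom_lung_foam,-613.3,31.4
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,nist_4,-900.9,18.2
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,nist_8,-860.9,16.2
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,nist_12,-759.1,15.8
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,nist_14,-804.0,17.2
drive_admire5_3.43,SOMATOM Drive,ADMIRE 5,3.43,nist_20,-664.5,19.8
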