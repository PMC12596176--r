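protocol,in_plane_f50,in_plane_f20,z_f50,z_f20
force_ref,3.63,5.48,3.47,5.70
drive_admire3_2.40,3.67,5.35,3.35,5.35
drive_admire5_2.40,3.87,5.60,3.35,5.46
drive_admire3_3.43,3.61,5.36,3.44,5.55
drive_admire5_3.43,3.82,5.59,3.46,5.67
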