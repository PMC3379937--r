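material_id,mass_dose_ug,bet_ssa_m2_per_g,esa_m2_per_g,d_swcnt_nm,d_bundle_nm,d_od_nm,d_hc_nm,structure_count,iron_pct,ssa_dose_printed_m2,esa_dose_printed_m2
SWCNT,40,1040,138.2,3,65,,,,0.23,4.16e-2,5.52e-3
CNF,120,45,21,,,109,53,,1.4,5.4e-3,2.52e-3
asbestos,120,8.3,8.3,,,,,,18,9.6e-4,9.6e-4
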