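#aerobic: false
reaction_id	max_uptake
EX_succ_e	10
EX_glc_e	10
EX_fru_e	10
EX_gal_e	10
EX_man_e	10
EX_xyl_e	10
EX_arab_e	10
EX_rib_e	10
EX_cellb_e	10
EX_lac_e	10
EX_mal_e	10
EX_ac_e	10
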