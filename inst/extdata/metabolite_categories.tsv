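metabolite_id	category
M_ala__L_e	amino acids
M_arg__L_e	amino acids
M_asn__L_e	amino acids
M_asp__L_e	amino acids
M_cys__L_e	amino acids
M_gln__L_e	amino acids
M_glu__L_e	amino acids
M_gly_e	amino acids
M_his__L_e	amino acids
M_ile__L_e	amino acids
M_leu__L_e	amino acids
M_lys__L_e	amino acids
M_met__L_e	amino acids
M_phe__L_e	amino acids
M_pro__L_e	amino acids
M_ser__L_e	amino acids
M_thr__L_e	amino acids
M_trp__L_e	amino acids
M_tyr__L_e	amino acids
M_val__L_e	amino acids
M_bz_e	aromatic compounds
M_4abz_e	aromatic compounds
M_34dhbz_e	aromatic compounds
M_pac_e	aromatic compounds
M_tol_e	aromatic compounds
M_thm_e	B-vitamins
M_ribflv_e	B-vitamins
M_nac_e	B-vitamins
M_pnto__R_e	B-vitamins
M_pydx_e	B-vitamins
M_btn_e	B-vitamins
M_fol_e	B-vitamins
M_cbl1_e	B-vitamins
M_alagly_e	oligopeptides
M_glyglu_e	oligopeptides
M_glygln_e	oligopeptides
M_glyasn_e	oligopeptides
M_glymet_e	oligopeptides
M_alaleu_e	oligopeptides
M_alahis_e	oligopeptides
M_glc__D_e	sugars/phosphosugars
M_fru_e	sugars/phosphosugars
M_gal_e	sugars/phosphosugars
M_man_e	sugars/phosphosugars
M_xyl__D_e	sugars/phosphosugars
M_rib__D_e	sugars/phosphosugars
M_g6p_e	sugars/phosphosugars
M_f6p_e	sugars/phosphosugars
M_tre_e	sugars/phosphosugars
M_ade_e	nucleobases
M_gua_e	nucleobases
M_ura_e	nucleobases
M_csn_e	nucleobases
M_xan_e	nucleobases
M_hxan_e	nucleobases
M_ac_e	other
M_etoh_e	other
M_lac__L_e	other
M_succ_e	other
M_for_e	other
M_nh4_e	other
M_pi_e	other
M_h2s_e	other
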