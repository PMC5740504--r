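# DMEM-like growth medium, keyed by Recon-style exchange reaction ids.
# The bound magnitudes are a documented convention (uptake in
# mmol/gDW/h; negative flux = uptake), not a reproduction of any
# particular experimental formulation.
name: DMEM
exchanges:
  EX_glc(e): [-5, 0]
  EX_gln_L(e): [-2, 0]
  EX_o2(e): [-20, 0]
  EX_pi(e): [-1, 1000]
  EX_so4(e): [-1, 1000]
  EX_ca2(e): [-1, 1000]
  EX_fe3(e): [-1, 1000]
  EX_k(e): [-1, 1000]
  EX_na1(e): [-1, 1000]
  EX_arg_L(e): [-0.5, 0]
  EX_cys_L(e): [-0.5, 0]
  EX_gly(e): [-0.5, 0]
  EX_his_L(e): [-0.5, 0]
  EX_ile_L(e): [-0.5, 0]
  EX_leu_L(e): [-0.5, 0]
  EX_lys_L(e): [-0.5, 0]
  EX_met_L(e): [-0.5, 0]
  EX_phe_L(e): [-0.5, 0]
  EX_ser_L(e): [-0.5, 0]
  EX_thr_L(e): [-0.5, 0]
  EX_trp_L(e): [-0.5, 0]
  EX_tyr_L(e): [-0.5, 0]
  EX_val_L(e): [-0.5, 0]
  EX_chol(e): [-0.1, 1000]
  EX_fol(e): [-0.1, 1000]
  EX_ncam(e): [-0.1, 1000]
  EX_pydxn(e): [-0.1, 1000]
  EX_ribflv(e): [-0.1, 1000]
  EX_thm(e): [-0.1, 1000]
  EX_inost(e): [-0.1, 1000]
  EX_co2(e): [0, 1000]
  EX_lac_L(e): [0, 1000]
  EX_h2o(e): [-1000, 1000]
  EX_h(e): [-1000, 1000]
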