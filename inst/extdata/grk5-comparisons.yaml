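# Worked example configuration for comparing GRK5 kinase-domain
# structures.  Paths must point at locally downloaded coordinate files
# (the pipeline never downloads); the accession -> label mapping below
# is the user's responsibility and the ensemble membership is a
# reconstruction -- the published figure's exact entry list is not
# recoverable, so absolute PC coordinates depend on it.
output_dir: grk5-out
seed: 1
structures:
  - id: grk5_sgv_wt        # Sgv-bound wild type
    path: local/9cko.cif
    chain: A
  - id: grk5_sgv_d311n     # Sgv-bound D311N
    path: local/9ckp.cif
    chain: A
  - id: grk5_ligand_free
    path: local/9ckq.cif
    chain: A
  - id: grk5_cam_sgv       # Ca2+.CaM-GRK5.Sgv comparator
    path: local/6pjx.cif
    chain: A
  - id: grk6_sgv
    path: local/3nyn.cif
    chain: A
  - id: pka_ts             # PKA transition-state-like reference
    path: local/1l3r.cif
    chain: E
selections:
  # GRK5 domain layout (author numbering)
  grk5_small_lobe: "A:1-32,180-270,490-510"
  grk5_large_lobe: "A:271-450"
  grk5_kinase_domain: "A:180-510"
  small_lobe_align: "A:180-270"
  p_loop: "A:190-200"
  # helical windows holding Glu91/Val92 (alpha4) and Lys454/Arg455
  # (alphaJ); override from the deposited secondary-structure records
  alpha4: "A:85-99"
  alphaJ: "A:448-462"
ensemble:
  members: [grk5_sgv_wt, grk5_sgv_d311n, grk5_ligand_free,
            grk5_cam_sgv, grk6_sgv, pka_ts]
  reference: grk5_sgv_wt
  correspondence: by_alignment
  selection: grk5_kinase_domain
  lobes: [grk5_small_lobe, grk5_large_lobe]
comparisons:
  - a: grk5_sgv_wt
    b: grk5_sgv_d311n
  - a: grk5_sgv_wt
    b: grk5_ligand_free
    align: small_lobe_align
    moving: grk5_large_lobe
    helix_ranges: ["A:85-99", "A:448-462"]
    pairs:
      - ["A:91", "A:454"]
      - ["A:92", "A:455"]
ion_scan: [grk5_sgv_wt, grk5_cam_sgv]
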