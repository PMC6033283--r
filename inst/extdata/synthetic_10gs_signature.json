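{
  "rank_scope": "all_panel_genes",
  "rank_direction": "ascending",
  "note": "Synthetic placeholder coefficients for the rank-linear 10-gene signature; replace with a user-supplied signature file for real analyses."
}
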