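# Demo data

All files in this directory are **synthetic**: they were produced by
`chimerase::simulate_chimera(sim_config(seed = 20, n_genes = 12, p_l1 = 0.25,
frac_l1_specific = 0.1, frac_l2l3_specific = 0.1, n_decoy_sites = 10))`
and serialised with `write_simulation()`. They exist so the examples and
README can run on a tiny, fully reproducible dataset; no real sequencing
data is included.
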