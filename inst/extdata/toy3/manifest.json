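{
  "generator": "juncpep::generate_genome",
  "seed": 20260922,
  "n_genes": 3,
  "p_boundary_kr": 0.25,
  "phase_weights": [0.47, 0.3, 0.23],
  "p_canonical_intron": 0.99,
  "files": ["genome.fa", "annotation.genePred", "truth_junctions.tsv", "truth_proteins.tsv"]
}
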