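{
  "out_dir": "rpeqtl_demo",
  "seed": 5,
  "simulate": { "n_samples": 23, "n_loci": 8, "variants_per_locus": 15 },
  "sqtl": { "perms": [100, 500] }
}
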