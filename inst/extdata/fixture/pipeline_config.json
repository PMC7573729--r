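{
  "classes": {
    "qa": { "codon_fasta": "qa_codon.fasta" },
    "qb": { "codon_fasta": "qb_codon.fasta" },
    "rs": { "codon_fasta": "rs_codon.fasta" }
  },
  "expression_tsv": "expression.tsv",
  "model": { "kind": "GTR", "alpha": 1, "p_inv": 0, "k": 4 },
  "boot_n": 25,
  "n_perm": 999,
  "seed": 1,
  "tail": "one",
  "genetic_source": "cophenetic"
}
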