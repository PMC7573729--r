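{
  "config": {
    "n_codons": 300,
    "n_tissues": 12,
    "lambda": 1,
    "kappa": 2,
    "tree_scale": 0.3,
    "seed": 20,
    "classes": {
      "qa": {
        "n_tips": 8,
        "omega": 0.2,
        "regime": "gradual_bm"
      },
      "qb": {
        "n_tips": 8,
        "omega": 0.2,
        "regime": "rapid_partition"
      },
      "rs": {
        "n_tips": 8,
        "omega": 0.2,
        "regime": "neo_burst",
        "regime_params": {
          "burst_edges": [1, 6],
          "sigma2": 1
        },
        "omega_burst": 1
      }
    }
  },
  "classes": {
    "qa": {
      "n_tips": 8,
      "regime": "gradual_bm",
      "regime_params": [],
      "omega": 0.2,
      "expected_mantel_sign": "positive",
      "seeds": {
        "tree": 20003,
        "sequence": 20004,
        "expression": 20005
      },
      "newick": "(((qa_g1:0.13338970569557293,((qa_g5:0.012560100312326227,qa_g6:0.012560100312326227):0.05999475394592315,qa_g2:0.072554854258249382):0.060834851437323527):0.052014281684533877,(qa_g3:0.028583580261530135,qa_g4:0.028583580261530135):0.15682040711857664):0.11459601261989319,(qa_g7:0.0049150516178858902,qa_g8:0.0049150516178858902):0.29508494838211408);"
    },
    "qb": {
      "n_tips": 8,
      "regime": "rapid_partition",
      "regime_params": [],
      "omega": 0.2,
      "expected_mantel_sign": "none",
      "seeds": {
        "tree": 20006,
        "sequence": 20007,
        "expression": 20008
      },
      "newick": "(qb_g1:0.29999999999999999,(qb_g2:0.21757913060071324,((qb_g3:0.14044090071657633,(qb_g7:0.016268539788719092,qb_g8:0.016268539788719092):0.12417236092785724):0.047117231715581277,(qb_g4:0.088274103030044557,(qb_g5:0.057379322131038649,qb_g6:0.057379322131038649):0.030894780899005915):0.099284029402113047):0.0300209981685556):0.08242086939928675);"
    },
    "rs": {
      "n_tips": 8,
      "regime": "neo_burst",
      "regime_params": {
        "burst_edges": [1, 6],
        "sigma2": 1
      },
      "omega": [1, 0.2, 0.2, 0.2, 0.2, 1, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2],
      "expected_mantel_sign": "none",
      "seeds": {
        "tree": 20009,
        "sequence": 20010,
        "expression": 20011
      },
      "newick": "((rs_g1:0.1910925777443854,(((rs_g5:0.019247133552212171,rs_g6:0.019247133552212171):0.0089256997209849493,rs_g4:0.028172833273197122):0.013933139131144225,rs_g3:0.042105972404341344):0.14898660534004407):0.10890742225561459,((rs_g7:0.0060428329682550566,rs_g8:0.0060428329682550566):0.080879189185753694,rs_g2:0.086922022154008752):0.21307797784599125);"
    }
  }
}
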