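(((qa_g1:0.13338970569557293,((qa_g5:0.012560100312326227,qa_g6:0.012560100312326227):0.05999475394592315,qa_g2:0.072554854258249382):0.060834851437323527):0.052014281684533877,(qa_g3:0.028583580261530135,qa_g4:0.028583580261530135):0.15682040711857664):0.11459601261989319,(qa_g7:0.0049150516178858902,qa_g8:0.0049150516178858902):0.29508494838211408);
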