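(qb_g1:0.29999999999999999,(qb_g2:0.21757913060071324,((qb_g3:0.14044090071657633,(qb_g7:0.016268539788719092,qb_g8:0.016268539788719092):0.12417236092785724):0.047117231715581277,(qb_g4:0.088274103030044557,(qb_g5:0.057379322131038649,qb_g6:0.057379322131038649):0.030894780899005915):0.099284029402113047):0.0300209981685556):0.08242086939928675);
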