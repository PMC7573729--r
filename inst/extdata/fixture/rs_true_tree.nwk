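((rs_g1:0.1910925777443854,(((rs_g5:0.019247133552212171,rs_g6:0.019247133552212171):0.0089256997209849493,rs_g4:0.028172833273197122):0.013933139131144225,rs_g3:0.042105972404341344):0.14898660534004407):0.10890742225561459,((rs_g7:0.0060428329682550566,rs_g8:0.0060428329682550566):0.080879189185753694,rs_g2:0.086922022154008752):0.21307797784599125);
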