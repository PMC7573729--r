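>rs_g1
VATEPPANTCIRENAEEGDPIIVRAQTSEPPHMAQIKNALLRPEVWSDERYLKLDKRNTMKCNLFRPGRCTPRCLRRSLLIGGPQIGIRMFVTRPSYAVDEEFNSLRTGASMPTRTRVRYRRLRLRFNRYPLYLDWHPDRILAPEQAKVRKNSTAPGHRGRLNTPTTQYHAQHYECCSANPFDIEFTGTRRVVKCGHSYKIFVSTMGDHPGQCSAREIASGSCSDVRPTSMHVQTLWLPRISGVLVGILVIHTKRFHVPPGAGLYGSRSQQDLAGRRHGRMRQRDSNLPGLMKDVESAGE
>rs_g5
VAPGPAAHTCVRENAENRGPIIVWAQTSEPPQMAQINNALLRPDVWSDERYPKLNRRNTIKCNLLRTGRYTPRSLRRSLLFGGSQIGIRMFETHPSYAVDEQFNSPRTGASIPTCTRVKHRRLSPGFNRYPLYLDWHPDRILGPKQSKVRKNSTSPGHRERLDTPITQHHAQYYECSSANPFDIEFTRTRRLVNSGHSYEIFGSTMGAHPGQCSAREIVSGSCSDGSPISMRVQTLWLPRISGVLVGILVIDTKRLHVPPGAGMYGSRPQQDLAGRGHGSMRQRDANFAGFMKNVESDGE
>rs_g6
VAPEPAAHTCIRENAEDRGPIIVWAQTSEPPQMAQINNALLRPDVWSDERYLKLNRRNTIKCNLFRTGRYTPRSLRRSLLFGGSQIGIRMFETHPSYAVDEQFNSPRTGASIPTGTRVKHRRLSPGFNRYPLYLDWHPDRILGPEQSKVRKNSTAPGHRERLDTPITQHHAQHYECSSANPFDIEFTRTRRLVKSGHSYEIFGSTMGAHPGQCSAREIVSGSCSDGSPISMRVQTLWLPRISGVLVGILVIDTKRFHVRPGAGMYGSRSQQDLAGRGHGRMRQRDANFAVLMKNVESAGE
>rs_g4
VAPEPAAHTCIRENAEDRGPIIVWAQTSEPPQMAKINNALLRPEVWSDERYLKLNRRNTIKCNLFRTGRYTPRSLRRSLLFGGSQIGIRMFETHPSYAVDEQFNSPRTGASIPTGTRVKHRRLSPGFNRYPLYLDWHPDRILGPEQSKVRKNSTAPGHRERLDTPITLHHAQHYACSSANPFDIEFTRTRRVVKSGHSYEIFGSTMGAHPGQCSAREIVSGSCSDGSPISRRVQTLWLPRISGVLVGILVIDTKRFHVPPGAGMYGSRSQQDLAGRGHGRMRQRDANFAGLMKNVESAGE
>rs_g3
VAPEPAAHTCIRENAEVRGPIIVWAQTSEPPQMGQINNALLRPDVWSDERYLKLNKRNTIKCNLFRTGRYTPRSLRRSLLFGGSQIGIRMFVTHPSYTVDEQFNSLRTGASIPTGTRVKHRRLSPGFNRHPLYLYWHPDRILGPEQSKVRKNSTAPGHRERLDTPITQHHAQHYECSSANPFDIEFTRTRRVVKSGHSYEIFESTMVAHPGQCSAREIVSGSCSDGSPISMRVQTLWLRRISGVLVGILVLDTKRFHVPPGAGMYGSRSQQDLAGRGHGRMRQRDANFAGLMKNVESAGQ
>rs_g7
IATNPATNTCIRENAEEGRSIIFWAQRSETLHMAAIKDGLLRREVWYDEQCLKQDKRYAMRCNMFRTGRFARRIMRRSTLLGGSQIGSRMFLKLSSYAVDKQIKSQRMGAPTPTGTRVRNDRLSLGLNRYPLYFDSHPDRFLAPGQAQFRKKAAAQGHRERIVTPTAQHHVQHYKGCSVNPSEIEFTVTRRAVKCGHARKIFEWTMGARPGQCSARKIAEVSCSVAGPTSMHAQTPWLRRINGVLVGILEMDTKRFHVPPGPGPYGSRSQQDLAGREHCRMRQRESNLPGLTKDVESAEG
>rs_g8
IATNPATNTCIRENAEEGRSIIFWAQRSETPHMAAIKDGLLRREVWYDEQCLKQDKRYAMRCNMFRTGRFARRIMRRSTLLGGSQIGSRMFLKLSSYAVDKQIKSQRMGAPTPTGTRVRNDRLSLGLNRYPLYFDSHPDRFLAPGQAQFRKKAAAQGHRERIVTPTAQHHVQHYKGCSVNPSEIEFTVTRRAVKCGHARKIFEWTMGARPRQCSARKIAEVSCSVAGPTSMHAQTPWLRRINGVLVGILEMDTKRFHVPPGPGPYGSRSQQDLAGREHCRMRQRESNLPGLTKDVESAEG
>rs_g2
VATNPAANTCIRKNAEEGRPIIVRAQKSETPHMAAIKDRLLHREVWYDEQCLKQDKRYAMRCNMFRTGRFTRRIMRRSTLLGGSQIGSRMFLKLSSYAVDKQIKSQRMGAPTPTGTRVRNARLSLGLNRYPLYFDSHPDRFLAPGQAQFRKKAAAQGHRERIVTPTAQHHVQHYKCCSVDPSEIEFTATRRAVKCGHARKIFEWTMGARPGQCSARKIAEVSCSVAGPTSIHAQTPWLRRMNGVLVGILEMDTKRFHAPPGPGPYGSRSQQDLAGREHGRMRQRESNLPGLTKDVEFAEG
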