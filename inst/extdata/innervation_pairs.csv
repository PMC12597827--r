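sender_gene,receiver_gene,label
TH,ADRB1,adrenergic:TH->ADRB1
CHAT,CHRM2,cholinergic:CHAT->CHRM2
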