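sequence,peptideranker_score,toxicity,hia
GPVRGPF,0.878,Nontoxic,HIA+
HPHPHL,0.748,Nontoxic,HIA+
FVAPFPEV,0.518,Nontoxic,HIA+
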