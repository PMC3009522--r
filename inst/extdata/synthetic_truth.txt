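inf01
inf02
inf03
inf04
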