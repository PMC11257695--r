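targets, factors
TFa, !TFb
TFb, !TFa
ga1, TFa
ga2, TFa
ga3, TFa
gb1, TFb
gb2, TFb
gb3, TFb
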