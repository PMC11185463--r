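model,aicc
Peak common + LBLE common,1640.46
Peak seasonal + LBLE common,1634.51
Peak common + LBLE seasonal,1646.28
Peak seasonal + LBLE seasonal,1649.32
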