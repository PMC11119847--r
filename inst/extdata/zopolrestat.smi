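OC(=O)Cc1nn(Cc2nc3cc(ccc3s2)C(F)(F)F)c(=O)c2ccccc21
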