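isomer,pi_mz,ri_mz,mean_ratio,sd
ELF94,392,604,0.01,0.01
ELF94,384,604,0.09,0.01
ELF94,366,604,0.19,0.01
ELF94,279,604,0.10,0.01
ELF94,253,604,0.01,0.01
ELF94,221,604,0.38,0.01
ELF96,392,604,0.27,0.01
ELF96,384,604,0.07,0.01
ELF96,366,604,0.01,0.01
ELF96,279,604,0.01,0.01
ELF96,253,604,0.11,0.01
ELF96,221,604,0.28,0.01
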