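# PAM50 genes absent from the ACES expression platform
ANLN
CXXC5
GPR160
NUF2
TMEM45B
UBE2T
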