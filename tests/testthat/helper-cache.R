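# Cache shared across acceptance blocks so the 2000-point reference fit is
# computed once.
.acceptanceCache <- new.env(parent = emptyenv())
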