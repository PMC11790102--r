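ABCDEF
GHIJKL
MNOPQR
STUVWX
YZ1234
56789_
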