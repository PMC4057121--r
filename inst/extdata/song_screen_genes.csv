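gene,efficiency_pct
18S,102.5
GUSB,100.0
HMBS,96.3
HPRT,93.5
PGK1,94.0
RPS7,100.9
SDHA,103.3
TFRC,103.6
VIM,95.8
YWHAZ,96.6
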