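hu:
- -1000.0
- -120.0
- 0.0
- 60.0
- 1000.0
- 3000.0
rsp:
- 0.001
- 0.92
- 1.0
- 1.04
- 1.55
- 2.6
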