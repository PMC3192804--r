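{"command":"frobnicate","seed":1,"nodes":24,"config":{},"package":"0.1.0"}
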