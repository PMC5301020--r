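((((a1:1,a2:1):1,a3:2):1,a4:3):3,(((b1:1,b2:1):1,b3:2):1,b4:3):3);
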