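((iso_1:1,iso_2:2):1,(iso_3:1.5,iso_4:1.5):2.5);
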