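"roi","delta_0"
"ECS",9.57146101504829
"SPA",9.7611719514441
"SPA_upper",10.4933706585617
"SPA_lower",8.50923967515498
"PPA",9.2172611554044
"PPA_upper",10.0098407418216
"PPA_lower",7.92332785353334
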