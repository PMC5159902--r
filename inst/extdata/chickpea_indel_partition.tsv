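class	count
insertion	77446
deletion	73994
total	151440
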