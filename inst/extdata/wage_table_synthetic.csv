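gender,band,annual_wage
male,45,37994.9
male,55,14123.0
male,65,0
male,75,0
male,85,0
female,45,11769.1
female,55,5411.1
female,65,0
female,75,0
female,85,0
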