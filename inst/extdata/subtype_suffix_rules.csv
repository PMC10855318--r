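pattern,description
"_type_?[0-9a-z]+(_[0-9a-z]+)*$","explicit type label, e.g. cbass_type_II or zorya_type_i"
"_(i|ii|iii|iv|v|vi|vii|viii|ix|x)(_[a-z0-9]+)?$","bare roman-numeral subtype with optional sub-letter, e.g. retron_II_A"
"_fam$","family grouping suffix, e.g. lamassu_fam"
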