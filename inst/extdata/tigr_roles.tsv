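role	role_id
cell_envelope_other	88
conserved_hypothetical	156
hypothetical	704
unknown_function	157
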