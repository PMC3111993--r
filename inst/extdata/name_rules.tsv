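pattern	replacement	rule_id
\bfamily protein family protein\b	family protein	suffix_1
\bdomain protein domain protein\b	domain protein	suffix_2
\bfamily protein domain protein\b	family domain protein	suffix_3
\bdomain protein family protein\b	domain family protein	suffix_4
\bprotein domain protein\b	domain protein	suffix_5
\bprotein family protein\b	family protein	suffix_6
\bprotein protein\b	protein	suffix_7
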