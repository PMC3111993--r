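keyword	role_id
abc transporter	64
transporter	64
permease	64
transcriptional regulator	129
regulator	129
kinase	130
phosphatase	130
dehydrogenase	109
reductase	109
oxidase	109
synthase	131
synthetase	131
ligase	131
protease	138
peptidase	138
ribosomal protein	133
polymerase	132
helicase	132
transposase	154
integrase	154
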