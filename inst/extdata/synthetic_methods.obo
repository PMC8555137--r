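format-version: 1.2
ontology: synthetic interaction detection methods (toy fixture)

[Term]
id: MI:0001
name: interaction detection method

[Term]
id: MI:0045
name: experimental interaction detection
is_a: MI:0001 ! interaction detection method

[Term]
id: MI:0401
name: biochemical
is_a: MI:0045 ! experimental interaction detection

[Term]
id: MI:0090
name: protein complementation assay
is_a: MI:0045 ! experimental interaction detection

[Term]
id: MI:0018
name: two hybrid
is_a: MI:0090 ! protein complementation assay

[Term]
id: MI:0006
name: anti bait coimmunoprecipitation
is_a: MI:0401 ! biochemical

[Term]
id: MI:0007
name: anti tag coimmunoprecipitation
is_a: MI:0401 ! biochemical
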