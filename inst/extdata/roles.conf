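# ROI role patterns: "role = case-insensitive perl regex", first match wins.
# Order matters: cornea/lens before eye, and the brain pattern must not
# match "brainstem".
cornea = cornea
lens = lens
eye = eye|orbit|globe
ptv = ptv
brain = brain(?!stem)
body = body|external
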