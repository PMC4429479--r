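{
  "formaldehyde": ["benzene", "methylene chloride"],
  "1,1,2,2-tetrachloroethane": ["1,1,2,2-tetrachloroethane"],
  "ethylene dichloride": ["vinyl chloride"],
  "diesel particulate matter": ["diesel particulate matter"]
}
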