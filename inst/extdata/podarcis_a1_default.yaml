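# Default tetrachromatic visual system for a diurnal lacertid lizard.
# Peak sensitivities are literature-derived values for Podarcis-type eyes;
# sensitivities are rebuilt from A1 pigment templates at load time.
cones:
  UVS: 367
  SWS: 456
  MWS: 497
  LWS: 562
abundances: [1, 1, 1, 4]
weber_ref: 0.05
reference_cone: LWS
illuminant: ideal
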