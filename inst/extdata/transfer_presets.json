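{
  "IPTG": {
    "inducer": "IPTG",
    "basal": 20,
    "maximal": 8000,
    "half_max": 40,
    "hill_n": 1.6,
    "note": "placeholder Hill parameters for the IPTG-inducible P_Tac sensor; synthetic convention, not a measured response"
  },
  "Van": {
    "inducer": "Van",
    "basal": 15,
    "maximal": 7000,
    "half_max": 8,
    "hill_n": 1.4,
    "note": "placeholder Hill parameters for the vanillic-acid-inducible P_Van sensor; synthetic convention, not a measured response"
  },
  "Chol": {
    "inducer": "Chol",
    "basal": 25,
    "maximal": 8000,
    "half_max": 400,
    "hill_n": 1.3,
    "note": "placeholder Hill parameters for the choline-inducible P_BetI sensor; synthetic convention, not a measured response"
  }
}
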