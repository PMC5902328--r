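[
  {
    "kind": "remove_reaction",
    "payload": "GLMS",
    "rationale": "No GlmS homologue in the genome; the glutamine-dependent Fru6P -> GlcN6P amination (EC 2.6.1.16) was introduced by gap-filling and the purified NagB shows no activity on Fru6P + glutamine."
  },
  {
    "kind": "remove_reaction",
    "payload": "GLNS",
    "rationale": "Glutamine-synthetase recycling step only present to supply the amino donor of the removed GlmS reaction."
  }
]
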