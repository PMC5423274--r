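# Restriction enzyme definitions (standard nomenclature).
# cut_offset: bases from the recognition-site start to the top-strand cut.
- name: ApeKI
  recognition: GCWGC
  cut_offset: 1
- name: PstI
  recognition: CTGCAG
  cut_offset: 5
- name: MspI
  recognition: CCGG
  cut_offset: 1
- name: EcoRI
  recognition: GAATTC
  cut_offset: 1
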