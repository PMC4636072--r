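archetype_id: openEHR-DEMOGRAPHIC-ITEM_TREE.person_details.v1
parent: ~
nodes:
- name: sex
  occurrence: 0..1
  type: DvCodedText
- name: address
  occurrence: 0..1
  type: DvText
ontology:
  '[sex]':
    en: sex
  '[address]':
    en: address

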