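archetype_id: openEHR-DEMOGRAPHIC-CLUSTER.person_identifier.v1
parent: ~
nodes:
- name: identifier
  occurrence: 1..1
  type: DvIdentifier
- name: type
  occurrence: 0..1
  type: DvText
ontology:
  '[identifier]':
    en: identifier
  '[type]':
    en: type

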