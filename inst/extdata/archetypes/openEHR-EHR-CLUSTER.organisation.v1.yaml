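archetype_id: openEHR-EHR-CLUSTER.organisation.v1
parent: ~
nodes:
- name: name
  occurrence: 0..1
  type: DvText
- name: identifier
  occurrence: 0..1
  type: DvIdentifier
ontology:
  '[name]':
    en: name
  '[identifier]':
    en: identifier

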