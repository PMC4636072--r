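archetype_id: openEHR-EHR-CLUSTER.person_name.v1
parent: ~
nodes:
- name: name
  occurrence: 0..1
  type: DvText
ontology:
  '[name]':
    en: name

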