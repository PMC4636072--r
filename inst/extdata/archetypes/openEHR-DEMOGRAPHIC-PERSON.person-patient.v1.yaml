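archetype_id: openEHR-DEMOGRAPHIC-PERSON.person-patient.v1
parent: ~
nodes:
- name: patientIdentifier
  occurrence: 1..1
  slot: openEHR-DEMOGRAPHIC-CLUSTER.person_identifier.v1
- name: patientName
  occurrence: 0..1
  slot: openEHR-DEMOGRAPHIC-PARTY_IDENTITY.person_name.v1
- name: details
  occurrence: 0..1
  slot: openEHR-DEMOGRAPHIC-ITEM_TREE.person_details.v1
- name: clinician
  occurrence: 0..1
  type: DvText
ontology:
  '[patientIdentifier]':
    en: patientIdentifier
  '[patientName]':
    en: patientName
  '[details]':
    en: details
  '[clinician]':
    en: clinician

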