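archetype_id: openEHR-EHR-INSTRUCTION.request-imaging_exam.v1
parent: ~
nodes:
- name: id
  occurrence: 1..1
  type: DvIdentifier
- name: requestorIdentifier
  occurrence: 0..1
  type: DvText
- name: receiverIdentifier
  occurrence: 0..1
  type: DvText
- name: patient
  occurrence: 1..1
  type: DvText
- name: requestDateTime
  occurrence: 0..1
  type: DvDateTime
- name: requestor
  occurrence: 0..1
  slot: openEHR-EHR-CLUSTER.person_name.v1
- name: receiver
  occurrence: 0..1
  slot: openEHR-EHR-CLUSTER.organisation.v1
ontology:
  '[id]':
    en: id
  '[requestorIdentifier]':
    en: requestorIdentifier
  '[receiverIdentifier]':
    en: receiverIdentifier
  '[patient]':
    en: patient
  '[requestDateTime]':
    en: requestDateTime
  '[requestor]':
    en: requestor
  '[receiver]':
    en: receiver

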