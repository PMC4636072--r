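archetype_id: openEHR-EHR-OBSERVATION.imaging_exam.v1
parent: ~
nodes:
- name: id
  occurrence: 1..1
  type: DvIdentifier
- name: receiverOrderIdentifier
  occurrence: 0..1
  type: DvIdentifier
- name: patient
  occurrence: 1..1
  type: DvText
- name: examDateTime
  occurrence: 0..1
  type: DvDateTime
- name: Image details
  occurrence: 0..*
  collection: CLUSTER
  children:
  - name: image
    occurrence: 0..1
    type: DvMultimedia
  - name: imageType
    occurrence: 0..1
    type: DvText
ontology:
  '[id]':
    en: id
  '[receiverOrderIdentifier]':
    en: receiverOrderIdentifier
  '[patient]':
    en: patient
  '[examDateTime]':
    en: examDateTime
  '[Image details]':
    en: Image details
  '[Image details]/[image]':
    en: image
  '[Image details]/[imageType]':
    en: imageType

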