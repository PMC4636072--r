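archetype_id: openEHR-EHR-OBSERVATION.lab_test-general.v1
parent: openEHR-EHR-OBSERVATION.lab_test.v1
nodes:
- name: id
  occurrence: 1..1
  type: DvIdentifier
- name: receiverOrderIdentifier
  occurrence: 0..1
  type: DvText
- name: patient
  occurrence: 1..1
  type: DvText
- name: testDateTime
  occurrence: 0..1
  type: DvDateTime
- name: Structure
  occurrence: 1..1
  collection: ITEM_TREE
  children:
  - name: Test name
    occurrence: 0..1
    type: DvText
  - name: Result
    occurrence: 0..*
    collection: CLUSTER
    children:
    - name: Test item
      occurrence: 0..1
      type: DvText
    - name: Result
      occurrence: 0..1
      type: DvText
    - name: Result unit
      occurrence: 0..1
      type: DvText
- name: annotation
  occurrence: 0..1
  slot: openEHR-EHR-CLUSTER.lab_result_annotation.v1
ontology:
  '[id]':
    en: id
  '[receiverOrderIdentifier]':
    en: receiverOrderIdentifier
  '[patient]':
    en: patient
  '[testDateTime]':
    en: testDateTime
  '[Structure]':
    en: Structure
  '[Structure]/[Test name]':
    en: Test name
  '[Structure]/[Result]':
    en: Result
  '[Structure]/[Result]/[Test item]':
    en: Test item
  '[Structure]/[Result]/[Result]':
    en: Result
  '[Structure]/[Result]/[Result unit]':
    en: Result unit
  '[annotation]':
    en: annotation

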