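archetype_id: openEHR-EHR-OBSERVATION.lab_test-thyroid.v1
parent: openEHR-EHR-OBSERVATION.lab_test.v1
nodes:
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
  - name: Thyroid stimulating hormone
    occurrence: 0..1
    type: DvQuantity
  - name: Free thyroxine
    occurrence: 0..1
    type: DvQuantity
- name: annotation
  occurrence: 0..1
  slot: openEHR-EHR-CLUSTER.lab_result_annotation.v1
ontology:
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
  '[Structure]/[Thyroid stimulating hormone]':
    en: Thyroid stimulating hormone
  '[Structure]/[Free thyroxine]':
    en: Free thyroxine
  '[annotation]':
    en: annotation

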