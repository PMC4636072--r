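archetype_id: openEHR-EHR-OBSERVATION.lab_test-blood_gases.v1
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
  - name: PaO2
    occurrence: 0..1
    type: DvQuantity
  - name: PaCO2
    occurrence: 0..1
    type: DvQuantity
  - name: Arterial pH
    occurrence: 0..1
    type: DvQuantity
  - name: SaO2
    occurrence: 0..1
    type: DvQuantity
  - name: CaO2
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
  '[Structure]/[PaO2]':
    en: PaO2
  '[Structure]/[PaCO2]':
    en: PaCO2
  '[Structure]/[Arterial pH]':
    en: Arterial pH
  '[Structure]/[SaO2]':
    en: SaO2
  '[Structure]/[CaO2]':
    en: CaO2
  '[annotation]':
    en: annotation

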