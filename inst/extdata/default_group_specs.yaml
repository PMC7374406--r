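format: spinedst-group-specs
version: 1
groups:
- group: no-LBP
  'n': 28
  params:
    thoracic_sitting_ae:
    - 2.8
    - 1.7
    thoracic_sitting_ve:
    - 2.3
    - 1.6
    thoracic_sitting_ce:
    - 0.5
    - 2.3
    thoracic_standing_ae:
    - 2.6
    - 1.9
    thoracic_standing_ve:
    - 1.9
    - 1.2
    thoracic_standing_ce:
    - -0.2
    - 2.8
    lumbar_sitting_ae:
    - 1.8
    - 0.7
    lumbar_sitting_ve:
    - 1.9
    - 0.9
    lumbar_sitting_ce:
    - 0.2
    - 1.0
    lumbar_standing_ae:
    - 1.8
    - 1.3
    lumbar_standing_ve:
    - 1.8
    - 1.3
    lumbar_standing_ce:
    - -0.3
    - 0.9
    pelvis_sitting_ae:
    - 1.8
    - 1.3
    pelvis_sitting_ve:
    - 1.2
    - 0.6
    pelvis_sitting_ce:
    - 0.4
    - 1.9
    pelvis_standing_ae:
    - 0.8
    - 0.6
    pelvis_standing_ve:
    - 0.6
    - 0.6
    pelvis_standing_ce:
    - 0.3
    - 0.9
- group: FP
  'n': 49
  params:
    thoracic_sitting_ae:
    - 5.5
    - 3.7
    thoracic_sitting_ve:
    - 5.1
    - 1.6
    thoracic_sitting_ce:
    - -3.2
    - 4.9
    thoracic_standing_ae:
    - 5.3
    - 3.3
    thoracic_standing_ve:
    - 4.4
    - 2.7
    thoracic_standing_ce:
    - 0.8
    - 4.5
    lumbar_sitting_ae:
    - 7.7
    - 4.1
    lumbar_sitting_ve:
    - 4.8
    - 3.1
    lumbar_sitting_ce:
    - 3.2
    - 6.8
    lumbar_standing_ae:
    - 6.3
    - 3.8
    lumbar_standing_ve:
    - 4.4
    - 3.0
    lumbar_standing_ce:
    - -1.5
    - 5.8
    pelvis_sitting_ae:
    - 4.0
    - 3.0
    pelvis_sitting_ve:
    - 3.5
    - 1.5
    pelvis_sitting_ce:
    - -3.1
    - 3.8
    pelvis_standing_ae:
    - 2.2
    - 1.5
    pelvis_standing_ve:
    - 0.6
    - 0.3
    pelvis_standing_ce:
    - -1.6
    - 1.7
- group: AEP
  'n': 23
  params:
    thoracic_sitting_ae:
    - 4.9
    - 3.1
    thoracic_sitting_ve:
    - 5.3
    - 1.7
    thoracic_sitting_ce:
    - 4.7
    - 3.1
    thoracic_standing_ae:
    - 5.6
    - 2.1
    thoracic_standing_ve:
    - 4.0
    - 1.9
    thoracic_standing_ce:
    - 2.2
    - 4.1
    lumbar_sitting_ae:
    - 5.7
    - 2.3
    lumbar_sitting_ve:
    - 3.8
    - 1.8
    lumbar_sitting_ce:
    - -3.1
    - 4.1
    lumbar_standing_ae:
    - 6.2
    - 2.3
    lumbar_standing_ve:
    - 5.4
    - 4.8
    lumbar_standing_ce:
    - -4.7
    - 2.7
    pelvis_sitting_ae:
    - 3.8
    - 2.6
    pelvis_sitting_ve:
    - 1.1
    - 0.6
    pelvis_sitting_ce:
    - -2.6
    - 3.5
    pelvis_standing_ae:
    - 2.4
    - 1.3
    pelvis_standing_ve:
    - 2.7
    - 1.2
    pelvis_standing_ce:
    - -2.9
    - 1.3
- group: PEP
  'n': 14
  params:
    thoracic_sitting_ae:
    - 7.8
    - 5.0
    thoracic_sitting_ve:
    - 5.5
    - 1.6
    thoracic_sitting_ce:
    - 7.5
    - 4.8
    thoracic_standing_ae:
    - 5.8
    - 3.0
    thoracic_standing_ve:
    - 4.5
    - 1.9
    thoracic_standing_ce:
    - 1.4
    - 5.2
    lumbar_sitting_ae:
    - 10.6
    - 4.8
    lumbar_sitting_ve:
    - 3.7
    - 1.8
    lumbar_sitting_ce:
    - -8.4
    - 7.9
    lumbar_standing_ae:
    - 7.2
    - 5.6
    lumbar_standing_ve:
    - 7.1
    - 5.8
    lumbar_standing_ce:
    - -4.8
    - 2.3
    pelvis_sitting_ae:
    - 5.1
    - 1.3
    pelvis_sitting_ve:
    - 1.3
    - 1.0
    pelvis_sitting_ce:
    - -3.1
    - 2.7
    pelvis_standing_ae:
    - 1.8
    - 1.0
    pelvis_standing_ve:
    - 3.3
    - 1.0
    pelvis_standing_ce:
    - -1.3
    - 1.0
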