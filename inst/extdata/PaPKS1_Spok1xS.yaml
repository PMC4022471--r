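cross:
  id: PaPKS1_Spok1xS
  parent1:
    strain_id: PaPKS1_Spok1
    alleles:
      spok1: Spok1_0
      spok2: Spok2
      pks1: pks1_Spok1
  parent2:
    strain_id: S
    alleles:
      spok1: Spok1_0
      spok2: Spok2
      pks1: PKS1
  loci:
  - id: spok1
    chromosome: '5'
    sds_prob: 0.1
  - id: spok2
    chromosome: '5'
    sds_prob: 0.6
  - id: pks1
    chromosome: '2'
    sds_prob: 0.01
  alleles:
  - id: Spok1
    locus_id: spok1
    distorter_active: yes
    responder_covers:
    - Spok1
    - pks1_Spok1
    - pks1_GFP_Spok1
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators: []
  - id: Spok1_0
    locus_id: spok1
    distorter_active: no
    responder_covers: []
    trans_activators: []
  - id: Spok1_D
    locus_id: spok1
    distorter_active: no
    responder_covers: []
    trans_activators: []
    selectable_markers:
    - hygR
  - id: Spok2
    locus_id: spok2
    distorter_active: yes
    responder_covers:
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators: []
  - id: Spok2_0
    locus_id: spok2
    distorter_active: no
    responder_covers: []
    trans_activators: []
  - id: Spok2_D
    locus_id: spok2
    distorter_active: no
    responder_covers: []
    trans_activators: []
    selectable_markers:
    - hygR
  - id: Spok2_A
    locus_id: spok2
    distorter_active: no
    responder_covers:
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators: []
  - id: Res_A406
    locus_id: spok2
    distorter_active: no
    responder_covers:
    - Spok1
    - pks1_Spok1
    - pks1_GFP_Spok1
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators: []
  - id: PKS1
    locus_id: pks1
    distorter_active: no
    responder_covers: []
    trans_activators: []
    pigment_functional: yes
  - id: pks1_Spok1
    locus_id: pks1
    distorter_active: yes
    responder_covers:
    - Spok1
    - pks1_Spok1
    - pks1_GFP_Spok1
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators: []
    pigment_functional: no
  - id: pks1_Spok2
    locus_id: pks1
    distorter_active: yes
    responder_covers:
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators: []
    pigment_functional: no
  - id: pks1_Spok2AA
    locus_id: pks1
    distorter_active: yes
    responder_covers:
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators:
    - Spok2
    - pks1_Spok2
    pigment_functional: no
  - id: pks1_mCherry_Spok2
    locus_id: pks1
    distorter_active: yes
    responder_covers:
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators:
    - Spok2
    - pks1_Spok2
    pigment_functional: no
  - id: pks1_GFP_Spok1
    locus_id: pks1
    distorter_active: yes
    responder_covers:
    - Spok1
    - pks1_Spok1
    - pks1_GFP_Spok1
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators: []
    pigment_functional: no
  - id: pks1_Spok1_GFP
    locus_id: pks1
    distorter_active: no
    responder_covers:
    - Spok1
    - pks1_Spok1
    - pks1_GFP_Spok1
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators: []
    pigment_functional: no
  - id: pks1_Spok2_mCherry
    locus_id: pks1
    distorter_active: no
    responder_covers:
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators: []
    pigment_functional: no
  - id: pks1_SpokN
    locus_id: pks1
    distorter_active: yes
    responder_covers:
    - Spok2
    - pks1_Spok2
    - pks1_Spok2AA
    - pks1_mCherry_Spok2
    - pks1_SpokN
    trans_activators:
    - Spok2
    - pks1_Spok2
    pigment_functional: no
  - id: Sm_Spok1
    locus_id: sm_ins
    distorter_active: yes
    responder_covers:
    - Sm_Spok1
    trans_activators: []
  - id: Sm_null
    locus_id: sm_ins
    distorter_active: no
    responder_covers: []
    trans_activators: []
  linkage:
  - locus1: spok1
    locus2: spok2
    r: 0.5
simulation:
  n_asci: 10000
  packaging: binucleate_tetrad
  mode: phenomenological
  seed: 1
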