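spec_version: '1.0'
factors:
- name: Communication & supportive care
  omega: 0.916
  items:
  - id: providers_introduced
    loading: 0.55
  - id: explained_done
    loading: 0.82
  - id: permission_vaginal_exam
    loading: 0.82
  - id: explained_exams
    loading: 0.86
  - id: explained_medicine
    loading: 0.84
  - id: could_ask_questions
    loading: 0.66
  - id: talked_feelings
    loading: 0.78
  - id: addressed_fears
    loading: 0.51
  - id: encouraged_walk
    loading: 0.53
  - id: encouraged_eat_drink
    loading: 0.5
  - id: paid_attention
    loading: 0.55
- name: Hospital environment
  omega: 0.735
  items:
  - id: hospital_clean
    loading: 0.54
  - id: clean_water
    loading: 0.88
  - id: drinking_water
    loading: 0.91
- name: Maintained respect & dignity
  omega: 0.814
  items:
  - id: treated_respect
    loading: 0.45
  - id: treated_friendly
    loading: 0.45
  - id: waiting_time
    loading: 0.53
  - id: shouted_at
    loading: 0.83
  - id: mocked
    loading: 1.09
  - id: best_care
    loading: 0.46
  - id: recommend_hospital
    loading: 0.45
- name: Social support
  omega: 0.702
  items:
  - id: companion_labour
    loading: 0.85
  - id: companion_birth
    loading: 0.94
- name: Maintained privacy & confidentiality
  omega: 0.71
  items:
  - id: info_shared
    loading: 1.02
  - id: privacy_violated
    loading: 0.67
- name: Lack of physical & verbal abuse
  omega: 0.678
  items:
  - id: slapped_pinched
    loading: 0.4
  - id: negative_comments
    loading: 0.66
  - id: shouted_items
    loading: 0.78
  - id: asked_bribe
    loading: -0.73

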