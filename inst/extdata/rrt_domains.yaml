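spec_version: '1.0'
domains:
  responsiveness:
  - Communication & supportive care
  - Hospital environment
  - Social support
  respectful:
  - Maintained respect & dignity
  - Maintained privacy & confidentiality
  - Lack of physical & verbal abuse

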