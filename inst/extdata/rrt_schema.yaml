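spec_version: '1.0'
items:
- id: providers_introduced
  prompt: Did the providers introduce themselves to you with their names?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: explained_done
  prompt: Did you feel the providers explained what had been done to you?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: permission_vaginal_exam
  prompt: Did the provider ask permission before a vaginal examination?
  kind: categorical
  labels:
  - 'No'
  - 'Yes'
  non_scored:
  - Not relevant
  reverse: no
- id: explained_exams
  prompt: Did the provider explain why they were carrying out examinations?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: explained_medicine
  prompt: Did the provider explain why they were giving you any medicine?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored:
  - Not relevant
  reverse: no
- id: could_ask_questions
  prompt: Did you feel you could ask the provider any questions you had?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: talked_feelings
  prompt: Did the provider talk to you about how you were feeling?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: addressed_fears
  prompt: Did the provider address your anxieties and fears?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: encouraged_walk
  prompt: Were you encouraged to walk around during labour?
  kind: categorical
  labels:
  - 'No'
  - 'Yes'
  non_scored:
  - I did not want to
  reverse: no
- id: encouraged_eat_drink
  prompt: Were you encouraged to eat and drink during labour?
  kind: categorical
  labels:
  - 'No'
  - 'Yes'
  non_scored:
  - I did not want to
  reverse: no
- id: paid_attention
  prompt: When you needed help, did you feel the providers paid attention?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: hospital_clean
  prompt: Would you say the hospital was clean?
  kind: likert
  labels:
  - Very dirty
  - Somewhat dirty
  - Neither clean nor dirty
  - Somewhat clean
  - Very clean
  non_scored: []
  reverse: no
- id: clean_water
  prompt: Was there clean water in the hospital, e.g. for taking a shower?
  kind: categorical
  labels:
  - 'No'
  - 'Yes'
  non_scored:
  - Don't know
  reverse: no
- id: drinking_water
  prompt: Were you able to access clean drinking water when you needed it?
  kind: categorical
  labels:
  - 'No'
  - 'Yes'
  non_scored:
  - Don't know
  reverse: no
- id: treated_respect
  prompt: Did the providers at the hospital treat you with respect?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: treated_friendly
  prompt: Did the providers treat you in a friendly manner?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: waiting_time
  prompt: How would you describe the waiting time before admission to the labour ward?
  kind: likert
  labels:
  - Very long
  - Somewhat long
  - Acceptable
  - Short
  - Very short
  non_scored: []
  reverse: yes
- id: shouted_at
  prompt: Were you shouted or screamed at by a provider?
  kind: likert
  labels:
  - Yes, more than once
  - Yes, once
  - No, never
  non_scored: []
  reverse: yes
- id: mocked
  prompt: Were you mocked at by a provider or staff?
  kind: likert
  labels:
  - Yes, more than once
  - Yes, once
  - No, never
  non_scored: []
  reverse: yes
- id: best_care
  prompt: Did you feel the providers took the best care of you they could?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: recommend_hospital
  prompt: Would you recommend a family member to give birth in the same hospital?
  kind: likert
  labels:
  - 'No'
  - Maybe
  - Yes, definitely
  non_scored: []
  reverse: no
- id: companion_labour
  prompt: Were you allowed someone you wanted to stay during labour?
  kind: binary
  labels:
  - 'No'
  - 'Yes'
  non_scored: []
  reverse: no
- id: companion_birth
  prompt: Were you allowed someone you wanted to stay during birth?
  kind: binary
  labels:
  - 'No'
  - 'Yes'
  non_scored: []
  reverse: no
- id: info_shared
  prompt: My private or personal information was shared without my consent
  kind: likert
  labels:
  - Strongly agree
  - Agree
  - Disagree
  - Strongly disagree
  non_scored: []
  reverse: yes
- id: privacy_violated
  prompt: My physical privacy was violated
  kind: likert
  labels:
  - Strongly agree
  - Agree
  - Disagree
  - Strongly disagree
  non_scored: []
  reverse: yes
- id: slapped_pinched
  prompt: Were you slapped or pinched by a provider?
  kind: binary
  labels:
  - 'No'
  - 'Yes'
  non_scored: []
  reverse: yes
- id: negative_comments
  prompt: Did a provider make any negative comments about you?
  kind: binary
  labels:
  - 'No'
  - 'Yes'
  non_scored: []
  reverse: yes
- id: shouted_items
  prompt: Were you shouted at because you did not bring items with you?
  kind: binary
  labels:
  - 'No'
  - 'Yes'
  non_scored: []
  reverse: yes
- id: asked_bribe
  prompt: Did any staff suggest or ask you for a bribe or informal payment?
  kind: categorical
  labels:
  - 'No'
  - 'Yes'
  non_scored:
  - Don't know
  - Don't want to say
  reverse: yes
- id: called_by_name
  prompt: Did the providers call you by your name?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no
- id: fundal_pressure
  prompt: Was forceful downward pressure placed on your abdomen?
  kind: categorical
  labels:
  - 'No'
  - 'Yes'
  non_scored:
  - Don't know
  reverse: yes
- id: position_choice
  prompt: Were you able to be in the birth position of your choice?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored:
  - Not relevant
  reverse: no
- id: helped_pain
  prompt: Did you feel providers helped you with your pain?
  kind: likert
  labels:
  - 'No'
  - Yes, partially
  - Yes, completely
  - I did not need any treatment for pain
  non_scored: []
  reverse: no
  recode:
    'No': 'No'
    Yes, partially: Yes, partially
    Yes, completely: Yes, completely
    I experienced pain, but I was not distressed and did not need any treatment: I
      did not need any treatment for pain
    I did not experience any pain: I did not need any treatment for pain
- id: felt_safe
  prompt: In general, did you feel safe in the hospital?
  kind: likert
  labels:
  - Not at all safe
  - Very unsafe
  - Somewhat unsafe
  - Neutral
  - Somewhat safe
  - Safe
  - Very safe
  non_scored: []
  reverse: no
- id: held_down
  prompt: Were you held down to the bed forcefully?
  kind: binary
  labels:
  - 'No'
  - 'Yes'
  non_scored: []
  reverse: yes
  recode:
    'No': 'No'
    'Yes': 'Yes'
    Don't know: .median
- id: language_understood
  prompt: Did the provider speak to you in a language you could understand?
  kind: likert
  labels:
  - No, never
  - Yes, a few times
  - Yes, most of the time
  - Yes, all the time
  non_scored: []
  reverse: no

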