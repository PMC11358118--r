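# ASCII-transliterated template bank for terminals without CJK fonts.
# Same structure and element coverage as template_bank.yaml; sentences are
# terminated with the CJK full stop so the standard segmenter and sentence
# scanner apply unchanged. Pairs with starter_rules_ascii.json.
slots:
  "n": {type: int, min: 40, max: 300}
  "n2": {type: int, min: 20, max: 150}
  m: {type: int, min: 1, max: 15}
  a1: {type: int, min: 18, max: 45}
  a2: {type: int, min: 46, max: 80}
  a3: {type: int, min: 30, max: 70}
  hosp:
    type: choice
    options: [Xinhua Hospital, Dongzhimen Hospital, Longhua Hospital]
  dis:
    type: choice
    options: [chronic gastritis, hypertension, type 2 diabetes]
  guide:
    type: choice
    options: [TCM Trial Guideline, Internal Medicine Handbook]
  ther:
    type: choice
    options: [Xiaoyao powder, Buzhong Yiqi decoction, acupuncture]
  ctrl:
    type: choice
    options: [placebo, metformin, nifedipine]
  ae:
    type: choice
    options: [nausea, dizziness, rash]
  blind:
    type: choice
    options: [single-blind, double-blind]
elements:
  pop_number:
    templates:
      - sentence: "A total of {n} patients were enrolled。"
        gold: "A total of {n} patients were enrolled"
        rule: a_pn
        numeric_slot: "n"
  pop_age:
    templates:
      - sentence: "Patients were aged {a1} to {a2} years。"
        gold: "aged {a1} to {a2} years"
        rule: a_age
  pop_source:
    templates:
      - sentence: "Cases were recruited from {hosp}。"
        gold: "recruited from {hosp}"
        rule: a_src
  pop_diagnosis:
    templates:
      - sentence: "All patients met the diagnostic criteria for {dis} in the {guide}。"
        gold: "All patients met the diagnostic criteria for {dis} in the {guide}"
        rule: a_diag
  therapy:
    templates:
      - sentence: "The treatment group received {ther} and the control group received {ctrl}。"
        gold: "The treatment group received {ther}"
        rule: a_ther
  out_adverse:
    templates:
      - sentence: "Adverse events such as {ae} were observed。"
        gold: "Adverse events such as {ae} were observed"
        rule: a_ae
  out_shedding:
    templates:
      - sentence: "During the study {m} patients dropped out。"
        gold: "{m} patients dropped out"
        rule: a_shed
        numeric_slot: m
  des_missing:
    templates:
      - sentence: "Data were missing for {m} patients。"
        gold: "missing for {m} patients"
        rule: a_miss
        numeric_slot: m
  des_blind:
    templates:
      - sentence: "The study used a {blind} design。"
        gold: "used a {blind} design"
        rule: a_blind
  des_random:
    templates:
      - sentence: "Patients were allocated by a random number table。"
        gold: "allocated by a random number table"
        rule: a_rand
distractors:
  - sentence: "Baseline characteristics were comparable between groups。"
  - sentence: "Statistical analysis was performed with SPSS。"
  - sentence: "The protocol was approved by the ethics committee。"
  - sentence: "A previous study A total of {n2} patients were enrolled for screening。"
    trap: true
doc_id:
  authors: [Zhang, Li, Wang]
  titles: [clinical observation, randomized trial]
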