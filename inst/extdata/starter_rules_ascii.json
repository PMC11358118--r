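[
  {"rule_id": "a_pn", "element": "pop_number", "pattern": "A total of (?P<num>[0-9]+) patients were enrolled", "action": "match", "priority": 10},
  {"rule_id": "a_age", "element": "pop_age", "pattern": "aged (?P<lo>[0-9]+) to (?P<hi>[0-9]+) years", "action": "match", "priority": 10},
  {"rule_id": "a_src", "element": "pop_source", "pattern": "recruited from [A-Za-z ]*Hospital", "action": "match", "priority": 10},
  {"rule_id": "a_diag", "element": "pop_diagnosis", "pattern": "All patients met the diagnostic criteria for [^。]*", "action": "match", "priority": 10},
  {"rule_id": "a_ther", "element": "therapy", "pattern": "The treatment group received [A-Za-z ]+?(?= and the control| ?。|，|$)", "action": "match", "priority": 10},
  {"rule_id": "a_ae", "element": "out_adverse", "pattern": "Adverse events such as [a-z ]+ were observed", "action": "match", "priority": 10},
  {"rule_id": "a_shed", "element": "out_shedding", "pattern": "(?P<num>[0-9]+) patients dropped out", "action": "match", "priority": 10},
  {"rule_id": "a_miss", "element": "des_missing", "pattern": "missing for (?P<num>[0-9]+) patients", "action": "match", "priority": 10},
  {"rule_id": "a_blind", "element": "des_blind", "pattern": "used a (?:single|double)-blind design", "action": "match", "priority": 10},
  {"rule_id": "a_rand", "element": "des_random", "pattern": "allocated by a random number table", "action": "match", "priority": 10}
]
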