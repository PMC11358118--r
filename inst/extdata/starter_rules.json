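[
  {"rule_id": "pn_enroll", "element": "pop_number", "pattern": "共纳入(?P<num>[0-9]+)例患者", "action": "match", "priority": 10},
  {"rule_id": "pn_subject", "element": "pop_number", "pattern": "纳入受试者(?P<num>[0-9]+)例", "action": "match", "priority": 20},
  {"rule_id": "age_range", "element": "pop_age", "pattern": "年龄(?P<lo>[0-9]+)～(?P<hi>[0-9]+)岁", "action": "match", "priority": 10},
  {"rule_id": "age_mean", "element": "pop_age", "pattern": "平均年龄为(?P<num>[0-9]+(?:\\.[0-9]+)?)岁", "action": "match", "priority": 20},
  {"rule_id": "src_judge", "element": "pop_source", "pattern": "医院|门诊|病房", "action": "judge", "priority": 1},
  {"rule_id": "src_from", "element": "pop_source", "pattern": "病例来源于[^，。；]*门诊", "action": "match", "priority": 10},
  {"rule_id": "src_come", "element": "pop_source", "pattern": "病例均来自[^，。；]*医院", "action": "match", "priority": 20},
  {"rule_id": "diag_std", "element": "pop_diagnosis", "pattern": "所有患者均符合《[^》]*》中[^，。]*的诊断标准，并经临床检查确诊", "action": "match", "priority": 10},
  {"rule_id": "diag_ref", "element": "pop_diagnosis", "pattern": "诊断参照[^。]{1,30}相关标准执行，由两名医师独立判定", "action": "match", "priority": 20},
  {"rule_id": "ther_use", "element": "therapy", "pattern": "治疗组(?:采用|予以)[^，。；]{2,20}治疗", "action": "match", "priority": 10},
  {"rule_id": "ther_give", "element": "therapy", "pattern": "治疗组给予[^，。；]{2,20}治疗", "action": "match", "priority": 20},
  {"rule_id": "ae_occur", "element": "out_adverse", "pattern": "出现[^，。；]{1,15}等不良反应", "action": "match", "priority": 10},
  {"rule_id": "ae_none", "element": "out_adverse", "pattern": "未见(?:明显)?不良反应", "action": "match", "priority": 20},
  {"rule_id": "shed_drop", "element": "out_shedding", "pattern": "脱落(?P<num>[0-9一二三四五六七八九十]{1,4})例", "action": "match", "priority": 10},
  {"rule_id": "shed_quit", "element": "out_shedding", "pattern": "(?P<num>[0-9一二三四五六七八九十]{1,4})例患者中途退出", "action": "match", "priority": 20},
  {"rule_id": "miss_lost", "element": "des_missing", "pattern": "失访(?P<num>[0-9一二三四五六七八九十]{1,4})例", "action": "match", "priority": 10},
  {"rule_id": "miss_data", "element": "des_missing", "pattern": "数据缺失(?P<num>[0-9一二三四五六七八九十]{1,4})例", "action": "match", "priority": 20},
  {"rule_id": "blind_design", "element": "des_blind", "pattern": "采用[单双]盲法设计", "action": "match", "priority": 10},
  {"rule_id": "blind_assessor", "element": "des_blind", "pattern": "对[^，。；]{1,8}实施盲法", "action": "match", "priority": 20},
  {"rule_id": "rand_table", "element": "des_random", "pattern": "采用随机数字表法", "action": "match", "priority": 10},
  {"rule_id": "rand_draw", "element": "des_random", "pattern": "按随机抽签法分组", "action": "match", "priority": 20}
]
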