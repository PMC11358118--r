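# Built-in template bank for the synthetic RCT-paragraph generator.
# Each element template renders one evidence sentence; `gold` is the
# annotated substring (must occur in the rendered sentence), `rule` names
# the starter-ruleset rule whose full match reproduces the gold span on
# clean text (absent for deliberately rule-uncovered paraphrases), and
# `numeric_slot` names the slot carrying the D-level numeric ground truth.
# Distractors marked trap: true superficially match a starter rule and are
# never annotated — they probe rule-only false positives.
slots:
  "n": {type: int, min: 40, max: 300}
  "n2": {type: int, min: 20, max: 150}
  m: {type: int, min: 1, max: 15, zh_prob: 0.3}
  a1: {type: int, min: 18, max: 45}
  a2: {type: int, min: 46, max: 80}
  a3: {type: int, min: 30, max: 70}
  hosp:
    type: choice
    options:
      - 浙江中医学院附属新华医院
      - 北京中医药大学东直门医院
      - 上海中医药大学附属龙华医院
      - 广州中医药大学第一附属医院
      - 成都中医药大学附属医院
  dis:
    type: choice
    options: [慢性胃炎, 原发性高血压, 2型糖尿病, 类风湿关节炎, 慢性失眠]
  guide:
    type: choice
    options: [中药新药临床研究指导原则, 中医病证诊断疗效标准, 实用内科学]
  ther:
    type: choice
    options: [加味逍遥散, 补中益气汤, 针刺联合艾灸, 半夏泻心汤, 六味地黄丸]
  ctrl:
    type: choice
    options: [常规西药, 安慰剂, 二甲双胍, 硝苯地平]
  ae:
    type: choice
    options: [恶心, 头晕, 皮疹, 轻度腹泻, 口干]
  blind:
    type: choice
    options: [单盲法, 双盲法]
elements:
  pop_number:
    templates:
      - sentence: "共纳入{n}例患者，随机分为治疗组与对照组。"
        gold: "共纳入{n}例患者"
        rule: pn_enroll
        numeric_slot: "n"
      - sentence: "本研究纳入受试者{n}例。"
        gold: "纳入受试者{n}例"
        rule: pn_subject
        numeric_slot: "n"
  pop_age:
    templates:
      - sentence: "治疗组年龄{a1}～{a2}岁。"
        gold: "年龄{a1}～{a2}岁"
        rule: age_range
      - sentence: "患者平均年龄为{a3}岁。"
        gold: "平均年龄为{a3}岁"
        rule: age_mean
      - sentence: "入组者年龄介于{a1}至{a2}岁之间。"
        gold: "年龄介于{a1}至{a2}岁之间"
  pop_source:
    templates:
      - sentence: "病例来源于{hosp}门诊。"
        gold: "病例来源于{hosp}门诊"
        rule: src_from
      - sentence: "全部病例均来自{hosp}。"
        gold: "病例均来自{hosp}"
        rule: src_come
  pop_diagnosis:
    templates:
      - sentence: "所有患者均符合《{guide}》中{dis}的诊断标准，并经临床检查确诊。"
        gold: "所有患者均符合《{guide}》中{dis}的诊断标准，并经临床检查确诊"
        rule: diag_std
      - sentence: "诊断参照{guide}相关标准执行，由两名医师独立判定。"
        gold: "诊断参照{guide}相关标准执行，由两名医师独立判定"
        rule: diag_ref
  therapy:
    templates:
      - sentence: "治疗组采用{ther}治疗，对照组给予{ctrl}。"
        gold: "治疗组采用{ther}治疗"
        rule: ther_use
      - sentence: "治疗组予以{ther}治疗，疗程四周。"
        gold: "治疗组予以{ther}治疗"
        rule: ther_use
      - sentence: "对照组口服{ctrl}，治疗组在此基础上加服{ther}。"
        gold: "治疗组在此基础上加服{ther}"
  out_adverse:
    templates:
      - sentence: "治疗期间出现{ae}等不良反应。"
        gold: "出现{ae}等不良反应"
        rule: ae_occur
      - sentence: "两组均未见明显不良反应。"
        gold: "未见明显不良反应"
        rule: ae_none
  out_shedding:
    templates:
      - sentence: "研究期间治疗组脱落{m}例。"
        gold: "脱落{m}例"
        rule: shed_drop
        numeric_slot: m
      - sentence: "共有{m}例患者中途退出试验。"
        gold: "{m}例患者中途退出"
        rule: shed_quit
        numeric_slot: m
  des_missing:
    templates:
      - sentence: "随访期间失访{m}例。"
        gold: "失访{m}例"
        rule: miss_lost
        numeric_slot: m
      - sentence: "数据缺失{m}例，均予剔除。"
        gold: "数据缺失{m}例"
        rule: miss_data
        numeric_slot: m
  des_blind:
    templates:
      - sentence: "本研究采用{blind}设计。"
        gold: "采用{blind}设计"
        rule: blind_design
      - sentence: "试验过程中对评价者实施盲法。"
        gold: "对评价者实施盲法"
        rule: blind_assessor
  des_random:
    templates:
      - sentence: "采用随机数字表法将患者分为两组。"
        gold: "采用随机数字表法"
        rule: rand_table
      - sentence: "按随机抽签法分组。"
        gold: "按随机抽签法分组"
        rule: rand_draw
distractors:
  - sentence: "两组患者基线资料比较，差异无统计学意义。"
  - sentence: "统计分析采用SPSS软件完成。"
  - sentence: "本文对近年来相关文献进行了系统回顾。"
  - sentence: "结果显示治疗组总有效率高于对照组。"
  - sentence: "中医药治疗该病具有悠久的历史。"
  - sentence: "观察指标包括临床症状评分及实验室检查。"
  - sentence: "研究方案经医院伦理委员会审核批准。"
  - sentence: "随访时间为治疗结束后三个月。"
  - sentence: "数据录入由双人独立完成并核对。"
  - sentence: "既往一项研究共纳入{n2}例患者进行观察。"
    trap: true
  - sentence: "有文献报道该类药物可出现皮疹等不良反应。"
    trap: true
doc_id:
  authors: [张伟, 李娜, 王芳, 刘洋, 陈静]
  titles: [中药治疗临床观察, 针刺疗法随机对照研究, 联合用药疗效分析, 中西医结合治疗研究]
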