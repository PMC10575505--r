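# Guideline rule set for outpatient CAP in adults >= 65.
# Daily-dose bounds are in mg/day of the named component (amoxicillin
# component for combination products); bounds are widened by dose_tolerance
# before concordance is judged.
dose_tolerance: 0.10
duration_tolerance: 0
agents:
  - agent: amoxicillin
    atc_code: J01CA04
    dose_lower_mg_day: 2000      # 1 g twice daily
    dose_upper_mg_day: 3000      # 1 g three times daily
    recommended_duration_days: 5
    is_first_line: true
  - agent: amoxicillin-clavulanate
    atc_code: J01CR02
    dose_lower_mg_day: 1750      # 875 mg (amoxicillin component) twice daily
    dose_upper_mg_day: 1750
    recommended_duration_days: 5
    is_first_line: true
  - agent: doxycycline
    atc_code: J01AA02
    dose_lower_mg_day: 200       # 200 mg day 1 then 100 mg twice daily, 5-day mean
    dose_upper_mg_day: 200
    recommended_duration_days: 5
    is_first_line: true
  - agent: azithromycin
    atc_code: J01FA10
    is_first_line: false
  - agent: clarithromycin
    atc_code: J01FA09
    is_first_line: false
  - agent: levofloxacin
    atc_code: J01MA12
    is_first_line: false
  - agent: moxifloxacin
    atc_code: J01MA14
    is_first_line: false
  - agent: cefuroxime
    atc_code: J01DC02
    is_first_line: false
  - agent: cephalexin
    atc_code: J01DB01
    is_first_line: false
  - agent: sulfamethoxazole-trimethoprim
    atc_code: J01EE01
    is_first_line: false
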