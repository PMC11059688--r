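# Vocabulary and rule parameters for the ambulance trigger tool.
# Code lists and thresholds are region-configurable: trigger criteria reference
# local guidelines and documentation systems, so nothing here is hard-coded.
version: 1
codes:
  patient_sex: [female, male]
  dispatch_priority: [1, 2, 3]
  triage_colour: [red, orange, yellow, green, blue, missing]
  conveyance_mode: [ambulance, patient_transport, seated_transport, single_responder, own_transportation, none]
  mission_type: [primary_with_assessment, other]
  sxabcde_status: [assessed_and_addressed, assessed_not_addressed, not_assessed]
  definitive_care_type: [thrombolysis, pci, intensive_care, none]
  chief_complaint: [chest_pain, abdominal_pain, dyspnoea, head_trauma, infection,
                    dizziness, loss_of_consciousness, seizure, other]
  examinations: [ecg, abdominal_palpation, abdominal_auscultation, lung_auscultation,
                 neurological_exam]
# physiologic plausibility bounds used at parse time (inclusive)
bounds:
  patient_age: [0, 120]
  respiratory_rate: [0, 90]
  oxygen_saturation: [0, 100]
  systolic_bp: [30, 320]
  diastolic_bp: [10, 220]
  pulse: [0, 300]
  temperature: [24, 45]
  blood_glucose: [0, 60]
thresholds:
  response_time_min: 20        # A2: strict ">" in whole minutes, priority 1 only
  time_on_site_min: 10         # A3: strict ">", life-threatening condition only
  return_window_hours: 72      # B6 subtrigger: half-open (t0, t0 + 72 h]
  life_threatening_triage: [red]
# red-zone vital bounds used by B3 (deterioration during transport): positive when
# a vital crosses into its red zone between first and last panel, having started
# outside it
deterioration_red_bounds:
  oxygen_saturation: {low: 90}
  respiratory_rate: {low: 8, high: 30}
  pulse: {low: 40, high: 130}
  systolic_bp: {low: 90}
# A1: the five documentation criteria required for a complete record; each maps
# to a doc_* column of the record schema
documentation_criteria:
  - chief_complaint
  - vital_signs
  - assessment_outcome
  - interventions
  - conveyance_rationale
# B1C: the five core vital signs; blood glucose added when indicated
core_vitals: [respiratory_rate, oxygen_saturation, systolic_bp, pulse, temperature]
glucose_indicated_complaints: [loss_of_consciousness, seizure]
# B1D: required clinical examination per chief complaint; complaints absent from
# this map are not applicable to the trigger
exam_map:
  chest_pain: [ecg]
  abdominal_pain: [abdominal_palpation, abdominal_auscultation]
  dyspnoea: [lung_auscultation]
  head_trauma: [neurological_exam]
  dizziness: [neurological_exam]
  loss_of_consciousness: [ecg]
  seizure: [neurological_exam]
# B1B: condition-specific assessment/intervention rules; positive when the
# condition holds and the required intervention was not given
b1b_rules:
  - id: hypoglycaemia_untreated
    complaint: loss_of_consciousness
    when: {field: blood_glucose, op: lt, value: 4}
    requires_drug: glucose
  - id: hypoxia_untreated
    complaint: infection
    when: {field: oxygen_saturation, op: lt, value: 90}
    requires_drug: oxygen
# L1: formulary used to judge drug treatment (dose range + listed indications)
formulary:
  paracetamol: {min_dose: 250, max_dose: 1000, unit: mg, indications: [pain, fever]}
  morphine:    {min_dose: 1,   max_dose: 20,   unit: mg, indications: [pain]}
  oxygen:      {min_dose: 1,   max_dose: 15,   unit: l_min, indications: [hypoxia, dyspnoea, infection]}
  glucose:     {min_dose: 10,  max_dose: 50,   unit: g, indications: [hypoglycaemia, loss_of_consciousness]}
  ondansetron: {min_dose: 4,   max_dose: 8,    unit: mg, indications: [nausea]}
  aspirin:     {min_dose: 75,  max_dose: 500,  unit: mg, indications: [chest_pain]}
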