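# Trigger registry for the ambulance trigger tool. Each entry binds a trigger id
# to an evaluator kind; flag triggers name the record field they read. Profiles
# select the active set: "rrr900" is the registry used for the 900-record
# retrospective review; "final" is the revised set after the last consensus
# round (reconstructed: never-fired / lowest-validity triggers removed).
triggers:
  - {id: A1,  title: "Incomplete documentation",                                              group: A_general,     kind: documentation}
  - {id: A2,  title: "Response time >20 min priority 1 (lights and sirens)",                  group: A_general,     kind: response_time}
  - {id: A3,  title: "Time on site >10 min in case of life-threatening conditions",           group: A_general,     kind: time_on_site}
  - {id: A4,  title: "Weather and environment affect patient care",                           group: A_general,     kind: flag, flag: weather_affected_care}
  - {id: A5,  title: "Breakdown or faulty/missing equipment",                                 group: A_general,     kind: flag, flag: equipment_failure}
  - {id: A6,  title: "Shortage of ambulance resources",                                       group: A_general,     kind: flag, flag: resource_shortage}
  - {id: A7,  title: "Other",                                                                 group: A_general,     kind: manual}
  - {id: B1,  title: "Deviations from treatment guidelines",                                  group: B_care_process, kind: aggregate, of: [B1A, B1B, B1C, B1D]}
  - {id: B1A, title: "Assessment/Interventions according to SX-ABCDE",                        group: B_care_process, kind: sxabcde, parent: B1}
  - {id: B1B, title: "Assessment/Interventions in specific conditions",                       group: B_care_process, kind: condition_rules, parent: B1}
  - {id: B1C, title: "Absence of measured vital signs",                                       group: B_care_process, kind: absent_vitals, parent: B1}
  - {id: B1D, title: "Absence of relevant clinical examination",                              group: B_care_process, kind: absent_examination, parent: B1}
  - {id: B2,  title: "Physical harm during patient transport",                                group: B_care_process, kind: flag, flag: physical_harm_in_transport}
  - {id: B3,  title: "Deterioration of patient's condition during transport",                 group: B_care_process, kind: deterioration}
  - {id: B4,  title: "Telephone interpreter has not been used in case of language deficiency", group: B_care_process, kind: interpreter}
  - {id: B5,  title: "Inconsistency between the EMS clinicians and emergency physicians assessment and triage", group: B_care_process, kind: triage_inconsistency}
  - {id: B6,  title: "The patient is non conveyed after EMS assessment",                      group: B_care_process, kind: nonconveyance}
  - {id: B6_RETURN_72H, title: "Patient return within 72 h",                                  group: B_care_process, kind: return_72h, parent: B6}
  - {id: B7,  title: "Alternative mode of transport to definitive care",                      group: B_care_process, kind: alternative_transport}
  - {id: B8,  title: "Ambulance destination deviates from local guidelines",                  group: B_care_process, kind: destination}
  - {id: L1,  title: "Unfavourable/Inappropriate drug treatment",                             group: L_medication,  kind: drug}
  - {id: L2,  title: "Mix-up of drugs",                                                       group: L_medication,  kind: flag, flag: drug_mixup}
  - {id: L3,  title: "Shortage of medicines due to absence/expiry date",                      group: L_medication,  kind: flag, flag: drug_shortage}
profiles:
  rrr900: [A1, A2, A3, A4, A5, A6, A7, B1, B1A, B1B, B1C, B1D, B2, B3, B4, B5, B6,
           B6_RETURN_72H, B7, B8, L1, L2, L3]
  final:  [A1, A2, A3, A5, A6, A7, B1, B1A, B1B, B1C, B1D, B3, B4, B5, B6,
           B6_RETURN_72H, B7, B8, L1]
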