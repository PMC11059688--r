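{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "EMS mission records",
  "description": "Array of structured ambulance mission records as read and written by the emstrigger package. Code lists (priorities, triage colours, modes, complaints) are governed by the vocabulary configuration; this schema fixes structure and types.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["record_id", "patient_key", "patient_age", "patient_sex",
                 "dispatch_priority", "mission_start", "triage_colour",
                 "chief_complaint", "mission_type", "conveyed", "conveyance_mode"],
    "properties": {
      "record_id": {"type": "string", "minLength": 1},
      "patient_key": {"type": "string"},
      "patient_age": {"type": "integer", "minimum": 0},
      "patient_sex": {"enum": ["female", "male"]},
      "dispatch_priority": {"enum": [1, 2, 3]},
      "mission_start": {"type": "string", "pattern": "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$"},
      "on_scene_arrival": {"type": ["string", "null"]},
      "scene_departure": {"type": ["string", "null"]},
      "triage_colour": {"enum": ["red", "orange", "yellow", "green", "blue", "missing"]},
      "chief_complaint": {"type": "string"},
      "mission_type": {"enum": ["primary_with_assessment", "other"]},
      "respiratory_rate": {"type": ["number", "null"]},
      "oxygen_saturation": {"type": ["number", "null"]},
      "systolic_bp": {"type": ["number", "null"]},
      "diastolic_bp": {"type": ["number", "null"]},
      "pulse": {"type": ["number", "null"]},
      "temperature": {"type": ["number", "null"]},
      "blood_glucose": {"type": ["number", "null"]},
      "panels": {
        "type": "array",
        "items": {
          "type": "object",
          "properties": {
            "minute": {"type": "number"},
            "respiratory_rate": {"type": ["number", "null"]},
            "oxygen_saturation": {"type": ["number", "null"]},
            "systolic_bp": {"type": ["number", "null"]},
            "pulse": {"type": ["number", "null"]}
          }
        }
      },
      "examinations": {"type": "array", "items": {"type": "string"}},
      "sx_scene_safety": {"$ref": "#/$defs/sxStatus"},
      "sx_x": {"$ref": "#/$defs/sxStatus"},
      "sx_a": {"$ref": "#/$defs/sxStatus"},
      "sx_b": {"$ref": "#/$defs/sxStatus"},
      "sx_c": {"$ref": "#/$defs/sxStatus"},
      "sx_d": {"$ref": "#/$defs/sxStatus"},
      "sx_e": {"$ref": "#/$defs/sxStatus"},
      "drugs": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["drug_code", "dose"],
          "properties": {
            "drug_code": {"type": "string"},
            "dose": {"type": "number", "exclusiveMinimum": 0},
            "unit": {"type": "string"},
            "route": {"type": "string"},
            "indication": {"type": "string"},
            "guideline_conform": {"type": ["boolean", "null"]}
          }
        }
      },
      "conveyed": {"type": "boolean"},
      "conveyance_mode": {"enum": ["ambulance", "patient_transport", "seated_transport",
                                   "single_responder", "own_transportation", "none"]},
      "destination": {"type": ["string", "null"]},
      "destination_per_guideline": {"type": ["boolean", "null"]},
      "weather_affected_care": {"type": "boolean"},
      "equipment_failure": {"type": "boolean"},
      "resource_shortage": {"type": "boolean"},
      "physical_harm_in_transport": {"type": "boolean"},
      "drug_mixup": {"type": "boolean"},
      "drug_shortage": {"type": "boolean"},
      "language_barrier_present": {"type": "boolean"},
      "interpreter_used": {"type": "boolean"},
      "doc_chief_complaint": {"type": "boolean"},
      "doc_vital_signs": {"type": "boolean"},
      "doc_assessment_outcome": {"type": "boolean"},
      "doc_interventions": {"type": "boolean"},
      "doc_conveyance_rationale": {"type": "boolean"},
      "ed_physician_triage": {"type": ["string", "null"]},
      "ed_direct_to_definitive_care": {"type": ["boolean", "null"]},
      "ed_definitive_care_type": {"enum": ["thrombolysis", "pci", "intensive_care", "none", null]},
      "deterioration_noted": {"type": "boolean"},
      "a7_flag": {"type": "boolean"},
      "override_b1b": {"type": ["boolean", "null"]},
      "override_b3": {"type": ["boolean", "null"]},
      "override_b8": {"type": ["boolean", "null"]},
      "override_l1": {"type": ["boolean", "null"]}
    }
  },
  "$defs": {
    "sxStatus": {"enum": ["assessed_and_addressed", "assessed_not_addressed", "not_assessed"]}
  }
}
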