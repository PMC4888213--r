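{
  "schema": "oncointerp findings document",
  "version": 1,
  "patient_required": ["patient_id", "cancer_type"],
  "required_sections": {
    "patient": "object",
    "somatic_mutations": "array",
    "drug_response": "array",
    "toxicity": "array",
    "prognosis": "array",
    "pathways": "array",
    "clinical_trials": "array",
    "germline_findings": "array",
    "actionability": "object",
    "provenance": "object"
  }
}
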