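{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "txtlsim parameter configuration",
  "description": "Flat object of biochemical constants for the TXTL expression model. Concentrations in nM, times in s, rate constants 1/s, elongation speeds nt/s. Unknown keys are rejected; omitted keys take package defaults.",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "kcat_m":    {"type": "number", "exclusiveMinimum": 0, "description": "transcription rate constant, 1/s (physical cap ~0.5)"},
    "KM_70":     {"type": "number", "exclusiveMinimum": 0, "description": "transcription Michaelis constant vs holoenzyme, nM"},
    "K70":       {"type": "number", "exclusiveMinimum": 0, "description": "sigma70-core RNAP dissociation constant, nM"},
    "S70_total": {"type": "number", "exclusiveMinimum": 0, "description": "total sigma factor 70, nM"},
    "E_total":   {"type": "number", "exclusiveMinimum": 0, "description": "total core RNA polymerase, nM"},
    "kd_m":      {"type": "number", "exclusiveMinimum": 0, "description": "mRNA degradation Vmax (k*[RNase]), nM/s"},
    "KM_m":      {"type": "number", "exclusiveMinimum": 0, "description": "mRNA degradation Michaelis constant, nM (keep >> [m])"},
    "kcat_p":    {"type": "number", "exclusiveMinimum": 0, "description": "translation rate constant, 1/s (physical cap ~0.5)"},
    "KM_R":      {"type": "number", "exclusiveMinimum": 0, "description": "translation Michaelis constant vs free ribosomes, nM"},
    "R_total":   {"type": "number", "exclusiveMinimum": 0, "description": "total active ribosomes, nM"},
    "k_mat":     {"type": "number", "exclusiveMinimum": 0, "description": "reporter maturation rate, 1/s (default is a placeholder)"},
    "Cm":        {"type": "number", "exclusiveMinimum": 0, "description": "transcription elongation speed, nt/s"},
    "Cp":        {"type": "number", "exclusiveMinimum": 0, "description": "translation elongation speed, nt/s"},
    "Lm":        {"type": "number", "exclusiveMinimum": 0, "description": "gene length, nt"},
    "P70":       {"type": "number", "minimum": 0, "description": "promoter (= plasmid) concentration, nM"},
    "comment":   {"type": "string"}
  }
}
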