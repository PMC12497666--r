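{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pulsescope sequence script",
  "type": "object",
  "required": ["name", "total_duration_s", "events"],
  "properties": {
    "name": {"type": "string"},
    "total_duration_s": {"type": "number", "exclusiveMinimum": 0},
    "events": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["onset_s", "shape", "peak_amplitude"],
        "properties": {
          "onset_s": {"type": "number", "minimum": 0},
          "peak_amplitude": {"type": "number", "exclusiveMinimum": 0},
          "freq_offset_hz": {"type": "number"},
          "phase_rad": {"type": "number"},
          "role": {"enum": ["excitation", "refocusing", "inversion",
                            "preconditioning", "restoration", "readout",
                            "water_excitation"]},
          "slice_index": {"type": ["integer", "null"]},
          "shape": {
            "type": "object",
            "required": ["kind"],
            "properties": {
              "kind": {"enum": ["rect", "sinc", "hypsec", "binomial121"]},
              "duration_s": {"type": "number", "exclusiveMinimum": 0},
              "n_lobes": {"type": "integer", "minimum": 1},
              "apodization": {"enum": ["none", "hann"]},
              "beta_rad_per_s": {"type": ["number", "null"]},
              "mu": {"type": "number"},
              "truncation_frac": {"type": "number",
                                  "exclusiveMinimum": 0,
                                  "exclusiveMaximum": 0.5},
              "sub_duration_s": {"type": "number", "exclusiveMinimum": 0},
              "spacing_s": {"type": "number", "exclusiveMinimum": 0}
            }
          }
        }
      }
    }
  }
}
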