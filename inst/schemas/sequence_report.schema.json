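{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pulsescope sequence report",
  "type": "object",
  "required": ["applied_offset_hz", "n_events", "events"],
  "properties": {
    "applied_offset_hz": {"type": "number"},
    "offset_estimated": {"type": "boolean"},
    "n_events": {"type": "integer", "minimum": 0},
    "slice_tr_s": {"type": "number"},
    "echo_spacing_s": {"type": "number"},
    "echo_time_s": {"type": "number"},
    "exc_to_refocus_s": {"type": "number"},
    "inversion_delay_s": {"type": "number"},
    "readout_spacing_s": {"type": "number"},
    "composite_spacing_s": {"type": "number"},
    "slice_frequencies_hz": {"type": "array", "items": {"type": "number"}},
    "acquisition_order": {"type": "array", "items": {"type": "integer"}},
    "interleave_even_odd": {"type": ["boolean", "null"]},
    "flip_estimates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["reference_angle_deg", "area_ratio", "deduced_angle_deg"],
        "properties": {
          "reference_angle_deg": {"type": "number"},
          "area_ratio": {"type": "number"},
          "deduced_angle_deg": {"type": "number"},
          "target_role": {"type": "string"}
        }
      }
    },
    "train_profile": {"type": "array", "items": {"type": "number"}},
    "intervals": {"type": "object"},
    "warnings": {"type": "array", "items": {"type": "string"}},
    "events": {"type": "object"},
    "sub_events": {"type": "array"}
  }
}
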