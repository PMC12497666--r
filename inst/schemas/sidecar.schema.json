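{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pulsescope WAV metadata sidecar",
  "type": "object",
  "properties": {
    "center_frequency_hz": {"type": "number"},
    "label": {"type": "string"},
    "attenuation_db": {"type": "number"},
    "sample_rate_hz": {"type": "number"},
    "bit_depth": {"type": "integer"}
  }
}
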