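{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "icasort run report",
  "type": "object",
  "required": ["format_version", "tool", "tool_version", "created", "config", "results"],
  "properties": {
    "format_version": {"type": "string"},
    "tool": {"type": "string"},
    "tool_version": {"type": "string"},
    "created": {"type": "string"},
    "config": {"type": "object"},
    "results": {"type": "object"}
  }
}
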