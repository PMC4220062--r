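{
  "title": "rhythmResample run manifest",
  "required": {
    "tool": "string",
    "version": "string",
    "created": "string",
    "stages": "object",
    "config": "object"
  },
  "optional": {
    "seed": "number",
    "fileDigests": "object",
    "provenance": "object"
  }
}
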