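{
  "title": "barcodegap pipeline report",
  "description": "Machine-readable report written by write_pipeline_report(). The 'required' tree lists mandatory keys and their scalar types (number, string, boolean, object, array); nested objects are given as sub-trees.",
  "required": {
    "stages": {
      "input": {
        "n_sequences": "number",
        "alignment_length": "number"
      },
      "dedup": {
        "n_in": "number",
        "n_representatives": "number",
        "n_collapsed": "number"
      },
      "distances": {
        "model": "string",
        "n_pairs": "number",
        "n_undefined": "number"
      }
    },
    "gap": {
      "found": "boolean",
      "method": "string"
    },
    "delimitations": "object",
    "provenance": {
      "package": "string",
      "version": "string",
      "config": "object",
      "config_hash": "string"
    }
  }
}
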