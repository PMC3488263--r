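{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "rmsep result-bundle manifest",
  "type": "object",
  "required": ["schema_version", "n_solitary", "class_counts",
               "n_separated"],
  "properties": {
    "schema_version": {"type": "string", "const": "1.0"},
    "n_solitary": {"type": "integer", "minimum": 0},
    "class_counts": {
      "type": "object",
      "additionalProperties": {"type": "integer", "minimum": 0},
      "propertyNames": {
        "enum": ["probably_truncated", "separated_system_member",
                 "corrupted_mtase_nearby", "no_paired_mtase",
                 "no_orthologs"]
      }
    },
    "n_separated": {"type": "integer", "minimum": 0},
    "mge_enrichment": {
      "type": "object",
      "properties": {
        "n_systems": {"type": "integer"},
        "n_with_mge": {"type": "integer"},
        "fraction": {"type": ["number", "null"]}
      }
    },
    "screen_trees": {
      "type": "object",
      "additionalProperties": {"type": "string",
                               "description": "newick with supports"}
    }
  }
}
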