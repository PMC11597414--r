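{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "duimito analysis report",
  "description": "Shape of the files run_pipeline() writes to its output directory.",
  "type": "object",
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "seed", "thresholds"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {},
        "config_hash": {},
        "thresholds": {
          "type": "object",
          "required": ["min_principal", "motif_min_identity"]
        }
      }
    },
    "ur_details": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["genome", "species", "sex_type", "urs", "records"]
      }
    },
    "tables": {
      "type": "array",
      "items": {
        "enum": ["composition.tsv", "codon_usage.tsv", "divergence.tsv",
                 "dnds.tsv", "cox2.tsv", "ur_table.tsv", "gene_orders.tsv",
                 "rearrangements.tsv", "pattern_calls.tsv",
                 "pattern_summary.tsv"]
      }
    }
  },
  "required": ["provenance"]
}
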