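{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cowcvr network dialect",
  "description": "Circle-of-Willis network: topology plus per-segment geometry. Units: metres. Segment orientation is proximal -> distal in the nominal antegrade flow direction; negative solved flows mean retrograde flow. PCoA segments are oriented carotid side -> posterior junction, so positive PCoA flow is anterior -> posterior.",
  "type": "object",
  "required": ["format", "version", "segments", "variants"],
  "properties": {
    "format": { "const": "cowcvr-network" },
    "version": { "type": "integer" },
    "segments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "label", "side", "dup", "prox", "dist",
                     "length_m", "r_prox_m", "r_dist_m"],
        "properties": {
          "id": { "type": "string" },
          "label": { "enum": ["ICA", "MCA1", "ACA1", "ACA2", "ACoA", "BA",
                               "PCA1", "PCA2", "PCoA"] },
          "side": { "enum": ["L", "R", ""] },
          "dup": { "type": "integer", "minimum": 1,
                   "description": "duplicate index for doubled arteries" },
          "prox": { "type": "string" },
          "dist": { "type": "string" },
          "length_m": { "type": "number", "exclusiveMinimum": 0 },
          "r_prox_m": { "type": "number", "exclusiveMinimum": 0 },
          "r_dist_m": { "type": "number", "exclusiveMinimum": 0 },
          "stump": { "type": "boolean",
                     "description": "true for PCoA half-segments created by the anterior/posterior split" }
        }
      }
    },
    "variants": {
      "type": "object",
      "properties": {
        "pcoa_l": { "type": "boolean" }, "pcoa_r": { "type": "boolean" },
        "acoa": { "type": "boolean" },
        "fetal_pca_l": { "type": "boolean" }, "fetal_pca_r": { "type": "boolean" },
        "dup_mca1_l": { "type": "boolean" }, "dup_mca1_r": { "type": "boolean" },
        "dup_aca2_l": { "type": "boolean" }, "dup_aca2_r": { "type": "boolean" }
      }
    },
    "stenoses": {
      "type": "object",
      "description": "keyed by ICA segment id",
      "additionalProperties": {
        "type": "object",
        "required": ["degree_nascet", "throat_radius", "throat_length"],
        "properties": {
          "degree_nascet": { "type": "number", "minimum": 0, "exclusiveMaximum": 100 },
          "throat_radius": { "type": "number", "exclusiveMinimum": 0 },
          "throat_length": { "type": "number", "minimum": 0 },
          "turbulent_loss_coefficient": { "type": "number" }
        }
      }
    }
  }
}
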