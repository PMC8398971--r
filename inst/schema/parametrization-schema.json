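{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "frdex parametrization interchange format v1",
  "description": "Minimal sufficient data from an upstream excited-state electronic-structure step: per-monomer transition data and, per supramolecular complex (SC), the reference-state overlap matrix with the SC adiabatic states plus adiabatic energies and transition dipoles.",
  "type": "object",
  "required": ["format", "monomers", "scs"],
  "properties": {
    "format": { "const": "frdex-parametrization-v1" },
    "monomers": {
      "type": "object",
      "description": "Keyed by base type (G, A, T).",
      "additionalProperties": {
        "type": "object",
        "required": ["base_type", "atom_names", "states", "gauge"],
        "properties": {
          "base_type": { "enum": ["G", "A", "T"] },
          "atom_names": { "type": "array", "items": { "type": "string" } },
          "gauge": { "enum": ["velocity", "length"] },
          "states": {
            "type": "object",
            "description": "Keyed by LE label (La, Lb).",
            "additionalProperties": {
              "type": "object",
              "required": ["energy", "elec_tdip", "mag_tdip", "charges"],
              "properties": {
                "energy": { "type": "number", "description": "eV" },
                "elec_tdip": { "type": "array", "minItems": 3, "maxItems": 3, "items": { "type": "number" }, "description": "a.u." },
                "mag_tdip": { "type": "array", "minItems": 3, "maxItems": 3, "items": { "type": "number" }, "description": "a.u." },
                "charges": { "type": "array", "items": { "type": "number" }, "description": "atomic transition charges (e), one per atom_names entry, summing to ~0" }
              }
            }
          }
        }
      }
    },
    "scs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sc_id", "kind", "labels", "n_ref", "n_adiabatic", "S", "energies", "elec_tdip", "mag_tdip", "gauge"],
        "properties": {
          "sc_id": { "type": "string" },
          "kind": { "enum": ["pair", "strand", "tetrad"] },
          "labels": {
            "type": "array",
            "items": { "type": "string" },
            "description": "Reference diabatic-state labels: 'LE:<site>:<La|Lb>' or 'CT:<donor>><acceptor>:<gamma>'."
          },
          "n_ref": { "type": "integer", "minimum": 1 },
          "n_adiabatic": { "type": "integer", "minimum": 1 },
          "S": {
            "type": "array", "items": { "type": "number" },
            "description": "Row-major n_ref x n_adiabatic overlap matrix <reference|adiabatic>."
          },
          "energies": { "type": "array", "items": { "type": "number" }, "description": "Adiabatic energies, eV, ascending." },
          "elec_tdip": { "type": "array", "items": { "type": "number" }, "description": "Row-major n_adiabatic x 3, a.u." },
          "mag_tdip": { "type": "array", "items": { "type": "number" }, "description": "Row-major n_adiabatic x 3, a.u." },
          "gauge": { "enum": ["velocity", "length"] }
        }
      }
    }
  }
}
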