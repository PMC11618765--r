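{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "contour-json/1",
  "description": "Plain JSON dialect for a contoured structure: a named organ stored as closed planar polygons, one per axial slice, with (x, y, z) boundary points in patient coordinates (mm). Rings are stored open (first vertex not repeated).",
  "type": "object",
  "required": ["name", "slice_thickness", "slices"],
  "properties": {
    "format": {"const": "contour-json/1"},
    "name": {"type": "string"},
    "slice_thickness": {"type": "number", "exclusiveMinimum": 0},
    "slices": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["z", "points"],
        "properties": {
          "z": {"type": "number"},
          "points": {
            "type": "array",
            "minItems": 3,
            "items": {
              "type": "array",
              "items": {"type": "number"},
              "minItems": 3,
              "maxItems": 3
            }
          }
        }
      }
    }
  }
}
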