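{
  "name": "icon_like_default",
  "comment": "Approximate 192-source / 8-sector unit geometry. The vendor's exact source map is proprietary; ring polar angles and focal distances here preserve the published topology (8 sectors x 24 sources, superior hemispherical array) and are fully overridable.",
  "frame": {
    "focus_mm": [100.0, 100.0, 100.0],
    "axes": "right-handed mm; x = patient left-right (gamma rotation axis), y = posterior-anterior, z = inferior-superior",
    "gamma_sign": "gamma 110 rotates beamlet positions by +20 degrees about +x through the focus; gamma 70 by -20 degrees"
  },
  "n_sectors": 8,
  "sector_span_deg": 45.0,
  "rings": [
    { "polar_deg": 36.0, "focal_mm": 435.0, "sources_per_sector": 4 },
    { "polar_deg": 45.0, "focal_mm": 419.0, "sources_per_sector": 5 },
    { "polar_deg": 54.0, "focal_mm": 403.0, "sources_per_sector": 5 },
    { "polar_deg": 63.0, "focal_mm": 386.0, "sources_per_sector": 5 },
    { "polar_deg": 72.0, "focal_mm": 370.0, "sources_per_sector": 5 }
  ]
}
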