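{
  "registry_version": "1.0",
  "elements": [
    {"code": "RDE1194", "meaning": "Liver mean attenuation", "units": "HU"},
    {"code": "RDE1207", "meaning": "Spleen mean attenuation", "units": "HU"},
    {"code": "RDE1193", "meaning": "Liver minus spleen attenuation", "units": "HU"},
    {"code": "LIVF1", "meaning": "Hepatic steatosis", "units": ""},
    {"code": "LOCAL-LIVVOL", "meaning": "Hepatic volume (local extension code)", "units": "mL"}
  ]
}
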