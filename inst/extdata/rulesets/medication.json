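{
  "name": "medication",
  "input_resource_types": ["MedicationDispense", "Medication"],
  "output_resource_type": "Medication",
  "ips_profile_uri": null,
  "retain_paths": ["resourceType", "id", "meta", "identifier", "code", "status", "form", "amount", "ingredient", "batch", "text"],
  "remove_contained_types": ["Substance"],
  "remove_paths": [],
  "flatten_reference_paths": [],
  "meta_policy": {"stamp_profile": false, "drop_version_and_updated": false, "source_uri": null},
  "code_policy": {"primary_code_path": "code", "first_coding_only": false, "default_system": "http://www.whocc.no/atc", "map_via": null, "text_from_code": false},
  "narrative_policy": {"required": true, "template_id": "medication-div"}
}
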