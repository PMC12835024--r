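{
  "name": "procedure",
  "input_resource_types": ["Procedure"],
  "output_resource_type": "Procedure",
  "ips_profile_uri": null,
  "retain_paths": ["resourceType", "id", "meta", "status", "code", "subject"],
  "remove_paths": [],
  "flatten_reference_paths": [
    {"path": "subject", "target_type": "Patient"}
  ],
  "meta_policy": {"keep_only": ["versionId", "lastUpdated", "source"]},
  "code_policy": {"primary_code_path": "code", "first_coding_only": true, "default_system": "http://snomed.info/sct", "map_via": "edi_snomed", "text_from_code": true},
  "narrative_policy": {"required": false, "template_id": null}
}
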