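# Synthetic excerpt modeled on the HINS KCD7 -> SNOMED CT mapping table.
# Rows are artifact-chosen stand-ins; target codes are genuine SNOMED CT concepts.
source_system,source_code,target_system,target_code,target_display,equivalence
http://hl7.org/fhir/sid/icd-10-kr,E11,http://snomed.info/sct,44054006,Type 2 diabetes mellitus,equal
http://hl7.org/fhir/sid/icd-10-kr,I10,http://snomed.info/sct,59621000,Essential hypertension,equal
http://hl7.org/fhir/sid/icd-10-kr,J45,http://snomed.info/sct,195967001,Asthma,equal
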