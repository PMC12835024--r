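# Synthetic excerpt modeled on the HIRA EDI -> SNOMED CT procedure mapping table.
# Source codes are artifact-chosen placeholders (no real mapping rows are
# redistributed); target codes are genuine SNOMED CT procedure concepts.
# The R4519 row is the worked-example entry targeting 11466000.
source_system,source_code,target_system,target_code,target_display,equivalence
https://hira.or.kr/CodeSystem/edi,R4519,http://snomed.info/sct,11466000,Cesarean section,equal
https://hira.or.kr/CodeSystem/edi,Q2861,http://snomed.info/sct,80146002,Appendectomy,equal
https://hira.or.kr/CodeSystem/edi,Q8030,http://snomed.info/sct,38102005,Cholecystectomy,equal
https://hira.or.kr/CodeSystem/edi,E7680,http://snomed.info/sct,73761001,Colonoscopy,equal
https://hira.or.kr/CodeSystem/edi,Q2755,http://snomed.info/sct,44558001,Repair of inguinal hernia,equal
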