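# Default age-stratified cause hierarchies (load with load_hierarchies()).
# The child order satisfies pneumonia < meningitis < malaria < aids; the
# neonatal hierarchy omits malaria and AIDS and places sepsis after
# pneumonia and diarrhea. Orders beyond those constraints are
# reconstructed (more specific diagnoses first).
neonate:
  ordered_causes:
  - tetanus
  - congenital
  - intrapartum
  - preterm
  - pneumonia
  - diarrhea
  - sepsis
  - other_neonatal
  multi_cause_group: []
  fallback_cause: unspecified
child:
  ordered_causes:
  - measles
  - injury
  - pneumonia
  - meningitis
  - malaria
  - aids
  - diarrhea
  - other_infections
  multi_cause_group:
  - measles
  - diarrhea
  - pneumonia
  fallback_cause: unspecified
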