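# Default under-five VA codebook (editable; load with read_codebook()).
items:
- id: fever
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: fever_duration_days
  kind: duration_days
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: convulsions
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: unconscious
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: stiff_neck
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: bulging_fontanelle
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: cough
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: cough_duration_days
  kind: duration_days
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: trouble_breathing
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: breathing_duration_days
  kind: duration_days
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: fast_breathing
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: chest_indrawing
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: loose_stools
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: diarrhea_duration_days
  kind: duration_days
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: stools_per_day
  kind: count
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: rash
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: rash_on_face
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: rash_duration_days
  kind: duration_days
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: jaundice
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: paleness
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: hair_color_change
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: edema_legs
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: dry_scaly_skin
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: tb_diagnosis_recent
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: injury_accident
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: road_accident
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: fall
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: drowning
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: burn
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: poisoning
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: animal_bite
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: born_early
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: very_small_at_birth
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: not_cry_after_birth
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: not_breathe_after_birth
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: suckled_normally_first_2d
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: stopped_suckling
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: spasms
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: cold_to_touch
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: lethargic
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: malformation
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: malformation_head
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: malformation_spine
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: malformation_limb
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
- id: malformation_other
  kind: binary
  missing_codes:
  - '9'
  - '99'
  - dk
  - DK
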