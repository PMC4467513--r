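# Default case-definition set (editable; load with load_definitions()).
# The AIDS and diarrhea screens follow the published study wording; every
# entry flagged 'reconstructed: yes' was rebuilt from WHO-style VA
# indicators because the original supplementary definition table is not
# redistributable, and should not be read as the original wording.
definitions:
- cause: tetanus
  strata:
  - neonate
  reconstructed: yes
  predicate:
    all_of:
    - item_equals:
        item: suckled_normally_first_2d
        value: 'yes'
    - item_equals:
        item: stopped_suckling
        value: 'yes'
    - item_equals:
        item: spasms
        value: 'yes'
- cause: congenital
  strata:
  - neonate
  reconstructed: yes
  predicate:
    all_of:
    - item_equals:
        item: malformation
        value: 'yes'
    - any_of:
      - item_equals:
          item: malformation_head
          value: 'yes'
      - item_equals:
          item: malformation_spine
          value: 'yes'
      - item_equals:
          item: malformation_limb
          value: 'yes'
      - item_equals:
          item: malformation_other
          value: 'yes'
- cause: intrapartum
  strata:
  - neonate
  reconstructed: yes
  predicate:
    any_of:
    - item_equals:
        item: not_cry_after_birth
        value: 'yes'
    - item_equals:
        item: not_breathe_after_birth
        value: 'yes'
- cause: preterm
  strata:
  - neonate
  reconstructed: yes
  predicate:
    any_of:
    - item_equals:
        item: born_early
        value: 'yes'
    - item_equals:
        item: very_small_at_birth
        value: 'yes'
- cause: pneumonia
  strata:
  - neonate
  - child
  reconstructed: yes
  predicate:
    all_of:
    - any_of:
      - item_equals:
          item: cough
          value: 'yes'
      - item_equals:
          item: trouble_breathing
          value: 'yes'
    - any_of:
      - item_equals:
          item: fast_breathing
          value: 'yes'
      - item_equals:
          item: chest_indrawing
          value: 'yes'
- cause: diarrhea
  strata:
  - neonate
  - child
  reconstructed: no
  predicate:
    all_of:
    - item_equals:
        item: loose_stools
        value: 'yes'
    - item_at_least:
        item: stools_per_day
        min_count: 6.0
- cause: sepsis
  strata:
  - neonate
  reconstructed: yes
  predicate:
    all_of:
    - any_of:
      - item_equals:
          item: fever
          value: 'yes'
      - item_equals:
          item: cold_to_touch
          value: 'yes'
    - any_of:
      - item_equals:
          item: stopped_suckling
          value: 'yes'
      - item_equals:
          item: lethargic
          value: 'yes'
- cause: other_neonatal
  strata:
  - neonate
  reconstructed: yes
  predicate:
    any_of:
    - item_equals:
        item: convulsions
        value: 'yes'
    - item_equals:
        item: jaundice
        value: 'yes'
- cause: measles
  strata:
  - child
  reconstructed: yes
  predicate:
    all_of:
    - item_equals:
        item: rash
        value: 'yes'
    - item_equals:
        item: fever
        value: 'yes'
    - any_of:
      - item_equals:
          item: rash_on_face
          value: 'yes'
      - duration_in_days:
          item: rash_duration_days
          min_days: 3.0
          max_days: '.inf'
- cause: injury
  strata:
  - child
  reconstructed: yes
  predicate:
    all_of:
    - item_equals:
        item: injury_accident
        value: 'yes'
    - any_of:
      - item_equals:
          item: road_accident
          value: 'yes'
      - item_equals:
          item: fall
          value: 'yes'
      - item_equals:
          item: drowning
          value: 'yes'
      - item_equals:
          item: burn
          value: 'yes'
      - item_equals:
          item: poisoning
          value: 'yes'
      - item_equals:
          item: animal_bite
          value: 'yes'
- cause: meningitis
  strata:
  - child
  reconstructed: yes
  predicate:
    all_of:
    - item_equals:
        item: fever
        value: 'yes'
    - any_of:
      - item_equals:
          item: stiff_neck
          value: 'yes'
      - item_equals:
          item: bulging_fontanelle
          value: 'yes'
- cause: malaria
  strata:
  - child
  reconstructed: yes
  predicate:
    all_of:
    - item_equals:
        item: fever
        value: 'yes'
    - any_of:
      - item_equals:
          item: convulsions
          value: 'yes'
      - item_equals:
          item: unconscious
          value: 'yes'
- cause: aids
  strata:
  - child
  reconstructed: no
  predicate:
    any_of:
    - item_equals:
        item: jaundice
        value: 'yes'
    - all_of:
      - item_equals:
          item: loose_stools
          value: 'yes'
      - duration_in_days:
          item: diarrhea_duration_days
          min_days: 31.0
          max_days: '.inf'
    - all_of:
      - item_equals:
          item: fever
          value: 'yes'
      - duration_in_days:
          item: fever_duration_days
          min_days: 31.0
          max_days: '.inf'
    - any_of:
      - item_equals:
          item: paleness
          value: 'yes'
      - item_equals:
          item: hair_color_change
          value: 'yes'
      - item_equals:
          item: edema_legs
          value: 'yes'
      - item_equals:
          item: dry_scaly_skin
          value: 'yes'
    - all_of:
      - any_of:
        - all_of:
          - item_equals:
              item: cough
              value: 'yes'
          - duration_in_days:
              item: cough_duration_days
              min_days: 3.0
              max_days: 27.0
        - all_of:
          - item_equals:
              item: trouble_breathing
              value: 'yes'
          - duration_in_days:
              item: breathing_duration_days
              min_days: 3.0
              max_days: 27.0
      - item_equals:
          item: fever
          value: 'yes'
      - none_of:
        - item_equals:
            item: tb_diagnosis_recent
            value: 'yes'
- cause: other_infections
  strata:
  - child
  reconstructed: yes
  predicate:
    item_equals:
      item: fever
      value: 'yes'
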