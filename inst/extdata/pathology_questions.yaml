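# Five research questions on synthetic pathology reports, encoded in the
# native SOX model format (seven query variants: Q2 and Q5 each split in two).
structure:
  name: report
  id: report
  namespace: http://example.org/pehr
  children:
    - name: content
      id: content
      namespace: http://example.org/pehr
      children:
        - {name: Material, id: material, namespace: "http://example.org/pehr/sections-a"}
        - {name: Macroscopy, id: macroscopy, namespace: "http://example.org/pehr/sections-a"}
        - {name: Microscopy, id: microscopy, namespace: "http://example.org/pehr/sections-a"}
        - {name: Overall_interpretation, id: overall_interpretation, namespace: "http://example.org/pehr/sections-a"}
        - {name: Overall_staging, id: overall_staging, namespace: "http://example.org/pehr/sections-b"}
        - {name: Localisation, id: localisation, namespace: "http://example.org/pehr/sections-b"}
        - {name: Typification, id: typification, namespace: "http://example.org/pehr/sections-b"}
        - {name: staging, id: staging, namespace: "http://example.org/pehr/sections-b"}

simple_terms:
  g_unit:
    - {pattern: 'g'}
  blister:
    - {pattern: 'Blister'}
  adenocarcinoma:
    - {pattern: 'Adenokarzinom(\w)*'}
  icdo_c61:
    - {pattern: 'ICD-O-C-61'}
  icdo_m8140:
    - {pattern: 'ICD-O-M-8140/3'}
  k_no_rest:
    - {pattern: 'ohne Rest'}
  k_rest:
    - {pattern: 'mit Rest'}
  prostate_flake:
    - {pattern: 'Prostatasp[\wäöüÄÖÜß]*'}
    - {pattern: 'Prostatastanz[\wäöüÄÖÜß]*'}
  cm_unit:
    - {pattern: 'cm'}
  leiomyom:
    - {pattern: 'Leiomyom(\w)*'}
  uterus:
    - {pattern: 'Uterus'}
  c18:
    - {pattern: 'C18'}
  colon:
    - {pattern: 'Kolon(\w)*'}
  t2:
    - {pattern: 'pT2(a|b)?'}
  tnm_sub_pn:
    - {pattern: 'pN[0-9]'}
  barrett:
    - {pattern: 'Barrett-Schleimhaut'}
  cave_phrase:
    - {pattern: 'ohne Nachweis einer Barrett-Schleimhaut'}
  esoph_biopsy:
    - {pattern: 'Ösophagusbiops[\wäöüÄÖÜß]*'}

concepts:
  g_unit_in_macro: {term: g_unit, node: macroscopy}
  blister_in_interp: {term: blister, node: overall_interpretation}
  adeno_in_interp: {term: adenocarcinoma, node: overall_interpretation}
  c61_in_loc: {term: icdo_c61, node: localisation}
  m8140_in_typ: {term: icdo_m8140, node: typification}
  k_no_rest_in_macro: {term: k_no_rest, node: macroscopy}
  k_rest_in_macro: {term: k_rest, node: macroscopy}
  flake_in_macro: {term: prostate_flake, node: macroscopy}
  flake_in_interp: {term: prostate_flake, node: overall_interpretation}
  cm_in_interp: {term: cm_unit, node: overall_interpretation}
  leiomyom_in_interp: {term: leiomyom, node: overall_interpretation}
  uterus_in_material: {term: uterus, node: material}
  c18_in_loc: {term: c18, node: localisation}
  colon_in_material: {term: colon, node: material}
  t2_in_staging: {term: t2, node: overall_staging}
  pn_in_staging: {term: tnm_sub_pn, node: staging}
  barrett_in_interp: {term: barrett, node: overall_interpretation}
  cave_in_interp: {term: cave_phrase, node: overall_interpretation}
  esoph_in_material: {term: esoph_biopsy, node: material}

queries:
  q1:
    expr:
      - and
      - g_unit_in_macro
      - - not
        - blister_in_interp
      - - or
        - adeno_in_interp
        - - and
          - c61_in_loc
          - m8140_in_typ
  q2_without_residual:
    expr:
      - and
      - k_no_rest_in_macro
      - - not
        - blister_in_interp
      - - or
        - adeno_in_interp
        - - and
          - c61_in_loc
          - m8140_in_typ
      - - or
        - flake_in_macro
        - flake_in_interp
  q2_with_residual:
    expr:
      - and
      - k_rest_in_macro
      - - not
        - blister_in_interp
      - - or
        - adeno_in_interp
        - - and
          - c61_in_loc
          - m8140_in_typ
      - - or
        - flake_in_macro
        - flake_in_interp
  q3:
    expr:
      - and
      - cm_in_interp
      - leiomyom_in_interp
      - uterus_in_material
  q4:
    expr:
      - and
      - - or
        - c18_in_loc
        - colon_in_material
      - t2_in_staging
      - pn_in_staging
  q5_numerator:
    expr:
      - and
      - barrett_in_interp
      - - not
        - cave_in_interp
  q5_denominator:
    expr: esoph_in_material
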