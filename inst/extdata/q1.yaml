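# Q1 model: gram unit in macroscopy, no blister in interpretation, and
# either adenocarcinoma in interpretation or the ICD-O localisation +
# typification code pair.
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

concepts:
  g_unit_in_macro: {term: g_unit, node: macroscopy}
  blister_in_interp: {term: blister, node: overall_interpretation}
  adeno_in_interp: {term: adenocarcinoma, node: overall_interpretation}
  c61_in_loc: {term: icdo_c61, node: localisation}
  m8140_in_typ: {term: icdo_m8140, node: typification}

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
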