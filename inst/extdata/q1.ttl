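@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix sox: <http://example.org/sox#> .
@prefix m: <http://example.org/models/q1#> .

# XML structure tree
m:report a sox:XML_Structure ;
  sox:local_name "report" ;
  sox:namespace "http://example.org/pehr" ;
  sox:has_child m:content .
m:content a sox:XML_Structure ;
  sox:local_name "content" ;
  sox:namespace "http://example.org/pehr" ;
  sox:has_child m:material , m:macroscopy , m:microscopy ,
    m:overall_interpretation , m:overall_staging , m:localisation ,
    m:typification , m:staging .
m:material a sox:XML_Structure ;
  sox:local_name "Material" ;
  sox:namespace "http://example.org/pehr/sections-a" .
m:macroscopy a sox:XML_Structure ;
  sox:local_name "Macroscopy" ;
  sox:namespace "http://example.org/pehr/sections-a" .
m:microscopy a sox:XML_Structure ;
  sox:local_name "Microscopy" ;
  sox:namespace "http://example.org/pehr/sections-a" .
m:overall_interpretation a sox:XML_Structure ;
  sox:local_name "Overall_interpretation" ;
  sox:namespace "http://example.org/pehr/sections-a" .
m:overall_staging a sox:XML_Structure ;
  sox:local_name "Overall_staging" ;
  sox:namespace "http://example.org/pehr/sections-b" .
m:localisation a sox:XML_Structure ;
  sox:local_name "Localisation" ;
  sox:namespace "http://example.org/pehr/sections-b" .
m:typification a sox:XML_Structure ;
  sox:local_name "Typification" ;
  sox:namespace "http://example.org/pehr/sections-b" .
m:staging a sox:XML_Structure ;
  sox:local_name "staging" ;
  sox:namespace "http://example.org/pehr/sections-b" .

# Search terms (labels carry the regex patterns)
m:g_unit a sox:Simple_Term ; rdfs:label "g" .
m:blister a sox:Simple_Term ; rdfs:label "Blister" .
m:adenocarcinoma a sox:Simple_Term ; rdfs:label "Adenokarzinom(\\w)*" .
m:icdo_c61 a sox:Simple_Term ; rdfs:label "ICD-O-C-61" .
m:icdo_m8140 a sox:Simple_Term ; rdfs:label "ICD-O-M-8140/3" .

# Search concepts: someValuesFrom restrictions on described_by and in
m:g_unit_in_macro rdfs:subClassOf sox:Search_Concept ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:described_by ;
                    owl:someValuesFrom m:g_unit ] ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:in ;
                    owl:someValuesFrom m:macroscopy ] .
m:blister_in_interp rdfs:subClassOf sox:Search_Concept ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:described_by ;
                    owl:someValuesFrom m:blister ] ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:in ;
                    owl:someValuesFrom m:overall_interpretation ] .
m:adeno_in_interp rdfs:subClassOf sox:Search_Concept ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:described_by ;
                    owl:someValuesFrom m:adenocarcinoma ] ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:in ;
                    owl:someValuesFrom m:overall_interpretation ] .
m:c61_in_loc rdfs:subClassOf sox:Search_Concept ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:described_by ;
                    owl:someValuesFrom m:icdo_c61 ] ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:in ;
                    owl:someValuesFrom m:localisation ] .
m:m8140_in_typ rdfs:subClassOf sox:Search_Concept ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:described_by ;
                    owl:someValuesFrom m:icdo_m8140 ] ;
  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty sox:in ;
                    owl:someValuesFrom m:typification ] .

# The query: a boolean class description over the concepts
m:q1 rdfs:subClassOf sox:Search_Query ;
  owl:equivalentClass [
    owl:intersectionOf (
      m:g_unit_in_macro
      [ owl:complementOf m:blister_in_interp ]
      [ owl:unionOf (
          m:adeno_in_interp
          [ owl:intersectionOf ( m:c61_in_loc m:m8140_in_typ ) ]
      ) ]
    )
  ] .
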