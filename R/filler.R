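# Fixed German pathology-flavoured filler vocabulary for synthetic reports.
# Chosen so that no filler token matches any default term label (no bare
# unit tokens, no digits, no planted surface forms); purely synthetic text,
# no real patient material.
filler_words <- c(
  "Gewebe", "Fragment", "Fragmente", "Anteil", "Anteile", "Probe",
  "unauffällig", "regelrecht", "vereinzelt", "mehrere", "kleine",
  "graubraune", "weissliche", "derbe", "weiche", "laengliche",
  "Oberflaeche", "glatt", "knotig", "Schnittflaeche", "homogen",
  "Exzidat", "Biopsat", "Stanzzylinder", "Paraffin", "eingebettet",
  "Entzuendung", "chronisch", "geringgradig", "maessiggradig",
  "hochgradig", "Stroma", "Druesen", "Epithel", "Zellbild",
  "Befund", "Diagnose", "Beurteilung", "siehe", "sowie", "ohne",
  "Nachweis", "Anhalt", "Malignitaet", "tumorfrei", "Resektat"
)
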