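# Canonical step ontology for robotic Roux-en-Y gastric bypass.
# Eight steps in procedure order; raw annotation labels are matched
# case-insensitively after normalizing whitespace/punctuation to "_".
# Extend `synonyms` with your annotation team's labels.
steps:
  - dissection
  - creation_of_gastric_pouch
  - measurement
  - division_of_mesentery
  - staple_anastomosis
  - enterotomy_closure
  - defect_closure
  - hand_sewn_anastomosis

synonyms:
  dissection of angle of his: dissection
  perigastric dissection: dissection
  retrogastric dissection: dissection
  adhesiolysis: dissection
  creation of gastric pouch: creation_of_gastric_pouch
  gastric pouch creation: creation_of_gastric_pouch
  pouch creation: creation_of_gastric_pouch
  horizontal pouch staple: creation_of_gastric_pouch
  vertical pouch staple: creation_of_gastric_pouch
  limb measurement: measurement
  measurement of bp limb: measurement
  measurement of roux limb: measurement
  bowel measurement: measurement
  division of mesentery: division_of_mesentery
  mesenteric division: division_of_mesentery
  division of jejunum: division_of_mesentery
  stapled anastomosis: staple_anastomosis
  staple anastomosis: staple_anastomosis
  jejunojejunostomy staple: staple_anastomosis
  gastrojejunostomy staple: staple_anastomosis
  enterotomy closure: enterotomy_closure
  common channel enterotomy closure: enterotomy_closure
  closure of common enterotomy: enterotomy_closure
  defect closure: defect_closure
  mesenteric defect closure: defect_closure
  closure of mesenteric defect: defect_closure
  petersen defect closure: defect_closure
  hand sewn anastomosis: hand_sewn_anastomosis
  handsewn anastomosis: hand_sewn_anastomosis
  gastrojejunostomy hand sewn: hand_sewn_anastomosis
  anterior layer gastrojejunostomy: hand_sewn_anastomosis
  posterior layer gastrojejunostomy: hand_sewn_anastomosis

exclusions:
  - leak test
  - hiatal hernia repair
  - concurrent hiatal hernia repair
  - eg junction leak test
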