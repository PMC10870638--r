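code	fatigue	respiratory	psychological	hormonal	toxicity	weight_gain	gastrointestinal	epithelial
energy	0.880	0	0	0	0	0	0	0
sleep	0	0	0	0	0	0	0	0
pain	0	0	0	0	0	0	0	0
drowsy	0.621	0	0	0	0	0	0	0
hair_loss	0	0	0	0	0	0	0	0.468
concentration	0.401	0	0.436	0	0	0	0	0
worry	0	0	0.792	0	0	0	0	0
nausea	0.430	0	0	0	0	0	0	0
sad	0	0	0.755	0	0	0	0	0
numbness	0	0	0	0	0.466	0	0	0
taste	0	0	0	0	0	0	0	0.709
irritable	0	0	0.512	0	0	0	0	0
dry_mouth	0	0	0	0	0	0	0	0
constipation	0	0	0	0	0	0	0	0
appetite_loss	0	0	0	0	0	0	0.537	0
hot_flashes	0	0	0	0.807	0	0	0	0
skin_changes	0	0	0	0	0	0	0	0.494
nervous	0	0	0.623	0	0	0	0	0
not_myself	0	0	0.520	0	0	0	0	0
sweats	0	0	0	0.788	0	0	0	0
sexual	0	0	0	0	0	0	0	0
bloated	0	0	0	0	0	0	0	0
dizziness	0	0	0	0	0	0	0	0
cough	0	0	0	0	0	0	0	0
diarrhea	0	0	0	0	0	0	0	0
weight_gain	0	0	0	0	0	0.942	0	0
appetite_gain	0	0	0	0	0	0.840	0	0
short_breath	0	0.824	0	0	0	0	0	0
itching	0	0	0	0	0	0	0	0
weight_loss	0	0	0	0	0	0	0.548	0
abd_cramps	0	0	0	0	0.481	0	0	0
mouth_sores	0	0	0	0	0	0	0	0.437
diff_breathing	0	1.049	0	0	0	0	0	0
chest_tight	0	0.611	0	0	0	0	0	0
swallowing	0	0	0	0	0	0	0	0.464
vomiting	0	0	0	0	0	0	0.526	0
swelling	0	0	0	0	0	0	0	0
urination	0	0	0	0	0.621	0	0	0
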