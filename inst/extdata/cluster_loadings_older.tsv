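code	fatigue	respiratory	psychological	hormonal	toxicity	weight_gain	gastrointestinal	epithelial
energy	0.743	0	0	0	0	0	0	0
sleep	0	0	0	0	0	0	0	0
pain	0	0	0	0	0	0	0	0
drowsy	0.463	0	0	0	0	0	0	0
hair_loss	0	0	0	0	0	0	0	0.540
concentration	0.541	0	0.437	0	0	0	0	0
worry	0	0	0.812	0	0	0	0	0
nausea	0	0	0	0	0	0	0.704	0
sad	0	0	0.866	0	0	0	0	0
numbness	0	0	0	0	0	0	0	0
taste	0	0	0	0	0	0	0	0.612
irritable	0	0	0.628	0	0	0	0	0
dry_mouth	0	0	0	0	0	0	0	0
constipation	0	0	0	0	0	0	0	0
appetite_loss	0	0	0	0	0	0	0.478	0
hot_flashes	0	0	0	0.728	0	0	0	0
skin_changes	0	0	0	0	0	0	0	0.679
nervous	0	0	0.678	0	0	0	0	0
not_myself	0	0	0	0	0	0	0	0.522
sweats	0	0	0	0.783	0	0	0	0
sexual	0	0	0	0	0	0	0	0
bloated	0	0	0	0	0	0	0	0
dizziness	0	0	0	0	0	0	0	0.479
cough	0	0.403	0	0	0	0	0	0
diarrhea	0	0	0	0	0	0	0	0
weight_gain	0	0	0	0	0	0.902	0	0
appetite_gain	0	0	0	0	0	0.802	0	0
short_breath	0	0.878	0	0	0	0	0	0
itching	0	0	0	0	0	0	0	0
weight_loss	0	0	0	0	0	0	0	0
abd_cramps	0	0	0	0	0.489	0	0	0
mouth_sores	0	0	0	0	0.476	0	0	0
diff_breathing	0	0.965	0	0	0	0	0	0
chest_tight	0	0.676	0	0	0	0	0	0
swallowing	0	0	0	0	0	0	0	0.494
vomiting	0	0	0	0	0	0	0.926	0
swelling	0	0	0	0	0	0	0	0
urination	0	0.402	0	0	0.418	0	0	0
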