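code,label
energy,Lack of energy
sleep,Difficulty sleeping
pain,Pain
drowsy,Feeling drowsy
hair_loss,Hair loss
concentration,Difficulty concentrating
worry,Worrying
nausea,Nausea
sad,Feeling sad
numbness,Numbness/tingling in hands/feet
taste,Change in the way food tastes
irritable,Feeling irritable
dry_mouth,Dry mouth
constipation,Constipation
appetite_loss,Lack of appetite
hot_flashes,Hot flashes
skin_changes,Skin changes
nervous,Feeling nervous
not_myself,I don't look like myself
sweats,Sweats
sexual,Problems with sexual interest or activity
bloated,Feeling bloated
dizziness,Dizziness
cough,Cough
diarrhea,Diarrhea
weight_gain,Weight gain
appetite_gain,Increased appetite
short_breath,Shortness of breath
itching,Itching
weight_loss,Weight loss
abd_cramps,Abdominal cramps
mouth_sores,Mouth sores
diff_breathing,Difficulty breathing
chest_tight,Chest tightness
swallowing,Difficulty swallowing
vomiting,Vomiting
swelling,Swelling of arms or legs
urination,Problems with urination
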