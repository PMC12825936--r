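pt	soc
cardiotoxicity	cardiac disorders
cardiac dysfunction	cardiac disorders
cardiac failure	cardiac disorders
cardiac failure congestive	cardiac disorders
tachycardia	cardiac disorders
cardiac disorder	cardiac disorders
atrial fibrillation	cardiac disorders
left ventricular dysfunction	cardiac disorders
pericardial effusion	cardiac disorders
cardiomyopathy	cardiac disorders
mitral valve incompetence	cardiac disorders
angina pectoris	cardiac disorders
ventricular hypokinesia	cardiac disorders
nausea	gastrointestinal disorders
diarrhoea	gastrointestinal disorders
vomiting	gastrointestinal disorders
fatigue	general disorders and administration site conditions
pyrexia	general disorders and administration site conditions
drug ineffective	general disorders and administration site conditions
ejection fraction decreased	investigations
neutropenia	blood and lymphatic system disorders
anaemia	blood and lymphatic system disorders
alopecia	skin and subcutaneous tissue disorders
rash	skin and subcutaneous tissue disorders
headache	nervous system disorders
dyspnoea	respiratory, thoracic and mediastinal disorders
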