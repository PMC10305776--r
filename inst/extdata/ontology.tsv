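# strokener default ontology, v1.
# 86 stroke-related entities in 5 categories (Diagnosis, Symptom, Social history,
# Medication, Treatment). Canonical identifiers are lower-kebab-case of the entity
# display names; "trauma-unspecified" and "brain-haemorrhage-unspecified" are the
# repo's abbreviated canonical forms of the corresponding display names.
# Synonym pools seed the simulator's surface forms; beyond a handful of standard
# clinical abbreviations they are repo-curated, minimal, and freely editable.
# Columns: entity<TAB>category<TAB>synonyms (pipe-separated; display form first).
entity	category	synonyms
stroke	Diagnosis	stroke|CVA|cerebrovascular accident
ischaemic-stroke	Diagnosis	ischaemic stroke|ischemic stroke|cerebral infarct|MCA infarct
intracranial-haemorrhage	Diagnosis	intracranial haemorrhage|ICH|intracerebral haemorrhage
subarachnoid-haemorrhage	Diagnosis	subarachnoid haemorrhage|SAH
extradural-haemorrhage	Diagnosis	extradural haemorrhage|extradural haematoma|EDH
subdural-haemorrhage	Diagnosis	subdural haemorrhage|subdural haematoma|SDH
brain-haemorrhage-unspecified	Diagnosis	brain haemorrhage|cerebral bleed
non-brain-haemorrhage	Diagnosis	GI bleed|PR bleeding|haematemesis|epistaxis
transient-ischaemic-attack	Diagnosis	transient ischaemic attack|TIA|mini-stroke
head-trauma	Diagnosis	head injury|head trauma|blow to the head
non-head-trauma	Diagnosis	fractured neck of femur|rib fractures|limb injury
trauma-unspecified	Diagnosis	trauma|polytrauma
dementia	Diagnosis	dementia|Alzheimer's disease|vascular dementia
delirium	Diagnosis	delirium|acute confusional state
hyperlipidaemia	Diagnosis	hyperlipidaemia|hypercholesterolaemia|high cholesterol
diabetes-mellitus	Diagnosis	diabetes mellitus|diabetes|T2DM|type 2 diabetes
hypoglycaemia	Diagnosis	hypoglycaemia|low blood sugar|hypo
ischaemic-heart-disease	Diagnosis	ischaemic heart disease|IHD|coronary artery disease|angina
myocardial-infarction	Diagnosis	myocardial infarction|MI|heart attack|NSTEMI|STEMI
hypertension	Diagnosis	hypertension|HTN|high blood pressure
atrial-fibrillation	Diagnosis	atrial fibrillation|AF|fast AF|paroxysmal AF
congestive-heart-failure	Diagnosis	congestive heart failure|Left ventricular systolic dysfunction|LVSD|cardiac decompensation|LV dysfunction|CCF
carotid-stenosis	Diagnosis	carotid stenosis|carotid artery disease
small-vessel-disease	Diagnosis	small vessel disease|SVD|microvascular ischaemic change
peripheral-vascular-disease	Diagnosis	peripheral vascular disease|PVD|peripheral arterial disease
pericarditis	Diagnosis	pericarditis
endocarditis	Diagnosis	endocarditis|infective endocarditis
aneurysm	Diagnosis	aneurysm|berry aneurysm|AAA
aortic-dissection	Diagnosis	aortic dissection|dissection of the aorta
arteriovenous-malformation	Diagnosis	arteriovenous malformation|AVM
intracranial-neoplasm	Diagnosis	intracranial neoplasm|brain tumour|glioma|cerebral metastases
gastrointestinal-ulceration	Diagnosis	gastrointestinal ulceration|peptic ulcer|duodenal ulcer|gastric ulcer
acute-pancreatitis	Diagnosis	acute pancreatitis|pancreatitis
bleeding-condition	Diagnosis	bleeding disorder|haemophilia|coagulopathy
clotting-condition	Diagnosis	thrombophilia|DVT|pulmonary embolism|PE
pregnancy	Diagnosis	pregnancy|pregnant|gravid
demyelinating-condition	Diagnosis	demyelinating condition|multiple sclerosis|MS
peripheral-nerve-disorder	Diagnosis	peripheral neuropathy|Bell's palsy|nerve palsy
cerebral-abscess	Diagnosis	cerebral abscess|brain abscess
todds-paresis	Diagnosis	Todd's paresis|Todd's paralysis|post-ictal weakness
epilepsy	Diagnosis	epilepsy|seizure disorder
functional-neurological-disorder	Diagnosis	functional neurological disorder|FND|functional symptoms|non-organic
encephalitis	Diagnosis	encephalitis
migraine	Diagnosis	migraine|hemiplegic migraine|migraine with aura
weakness	Symptom	weakness|hemiparesis|arm weakness|leg weakness|facial droop
speech-disturbance	Symptom	speech disturbance|dysarthria|dysphasia|aphasia|slurred speech
visual-loss	Symptom	visual loss|amaurosis fugax|hemianopia|loss of vision
other-visual-disturbance	Symptom	visual disturbance|blurred vision|double vision|diplopia
sensation-loss	Symptom	sensory loss|numbness|paraesthesia|altered sensation
confusion	Symptom	confusion|altered mental status|disorientation
altered-conscious-level	Symptom	reduced conscious level|drowsiness|reduced GCS|unresponsive
fall	Symptom	fall|mechanical fall|collapse
seizure	Symptom	seizure|fit|convulsion|tonic-clonic seizure
papilloedema	Symptom	papilloedema
neck-stiffness	Symptom	neck stiffness|stiff neck|nuchal rigidity|meningism
fever	Symptom	fever|pyrexia|febrile|high temperature
vomiting	Symptom	vomiting|nausea and vomiting|emesis
dizziness	Symptom	dizziness|light-headedness|presyncope
headache	Symptom	headache|thunderclap headache|severe headache
vertigo	Symptom	vertigo|room spinning
ataxia	Symptom	ataxia|unsteady gait|incoordination
other-cerebellar-dysfunction	Symptom	cerebellar signs|nystagmus|dysmetria|past-pointing
fluctuating-neurological-symptoms	Symptom	fluctuating symptoms|stuttering onset|waxing and waning deficit
smoking	Social history	smoker|smoking|ex-smoker|20 pack years|tobacco use
alcohol	Social history	alcohol|alcohol excess|units per week|ETOH
illicit-drug-use	Social history	illicit drug use|IVDU|cocaine use|recreational drugs
long-term-placement	Social history	nursing home resident|care home|long term placement
requires-help	Social history	requires help|package of care|POC|carers four times daily
impaired-mobility	Social history	impaired mobility|walks with a stick|wheelchair bound|zimmer frame
warfarin	Medication	warfarin|coumadin|warfarin sodium
clopidogrel	Medication	clopidogrel|plavix
rivaroxaban	Medication	rivaroxaban|xarelto
apixaban	Medication	apixaban|eliquis
dabigatran	Medication	dabigatran|pradaxa
edoxaban	Medication	edoxaban|lixiana
aspirin	Medication	aspirin|acetylsalicylic acid
heparin	Medication	heparin|LMWH|low molecular weight heparin|enoxaparin|dalteparin
other-anticoagulant	Medication	anticoagulant|DOAC|NOAC|anticoagulation
oestrogen-containing-drug	Medication	combined oral contraceptive|HRT|oestrogen|the pill
herbal-remedy	Medication	herbal remedy|St John's wort|ginkgo biloba
surgical-procedure	Treatment	surgery|laparotomy|hip replacement|CABG|appendicectomy
thrombolysis	Treatment	thrombolysis|alteplase|tPA|rtPA|thrombolysed
mechanical-thrombectomy	Treatment	mechanical thrombectomy|thrombectomy|clot retrieval
other-invasive-procedure	Treatment	lumbar puncture|arterial puncture|central line insertion|endoscopy
treatment-escalation-decision	Treatment	DNACPR|not for resuscitation|treatment escalation plan|ward-based ceiling of care
capacity-decision	Treatment	lacks capacity|capacity assessment|adults with incapacity
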