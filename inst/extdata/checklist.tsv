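# Thrombolysis eligibility checklist (Queen Elizabeth University Hospital, Glasgow).
# Question text carried verbatim; numeric thresholds (BP, PT, platelets, glucose)
# are display-only. linked_entities are ontology ids relevant to each item
# (pipe-separated; empty when the item concerns bedside findings, not history).
# Columns: question<TAB>polarity<TAB>linked_entities
question	polarity	linked_entities
Does the patient have symptoms of acute stroke?	must-be-yes	stroke|ischaemic-stroke|weakness|speech-disturbance|visual-loss|sensation-loss
Is there a measurable deficit on the NIH scale?	must-be-yes	weakness|speech-disturbance|visual-loss|sensation-loss|ataxia
Was the patient previously independent?	must-be-yes	requires-help|long-term-placement|impaired-mobility
Is there a clear time of onset within the last 4 ½ hours?	must-be-yes	
Has a CT scan since stroke onset excluded haemorrhage?	must-be-yes	intracranial-haemorrhage|brain-haemorrhage-unspecified
Has a senior member of the stroke team reviewed the CT scan?	must-be-yes	
Has the patient suffered head trauma or stroke within the last 3 months?	must-be-no	head-trauma|trauma-unspecified|stroke|ischaemic-stroke
Has the patient undergone major surgery within the past 2 weeks?	must-be-no	surgical-procedure
Is there a past history of intracranial haemorrhage?	must-be-no	intracranial-haemorrhage|subarachnoid-haemorrhage|extradural-haemorrhage|subdural-haemorrhage|brain-haemorrhage-unspecified
Is the history suggestive of SAH?	must-be-no	subarachnoid-haemorrhage|headache|neck-stiffness
Is the systolic BP >185 mmHg (after treatment if necessary)?	must-be-no	hypertension
Is the diastolic BP >110 mmHg (after treatment if necessary)?	must-be-no	hypertension
Has there been any GI or urinary tract haemorrhage within the last 21 days?	must-be-no	non-brain-haemorrhage|gastrointestinal-ulceration
Has there been an arterial puncture at a non compressible site within the last 7 days?	must-be-no	other-invasive-procedure
Was there a seizure at the time of symptom onset?	must-be-no	seizure|epilepsy|todds-paresis
Is the patient on full dose anticoagulant treatment (e.g. warfarin with INR >1.5, therapeutic dose heparin/LMWH or oral thrombin inhibitor such as dabigatran, rivoroxaban)	must-be-no	warfarin|heparin|dabigatran|rivaroxaban|apixaban|edoxaban|other-anticoagulant
Is the PT >15 sec (for those not on anticoagulants)?	should-be-no	bleeding-condition
Is the platelet count <100,000	should-be-no	bleeding-condition
Is the plasma glucose <2.7 or >22.2 mmol/l	should-be-no	hypoglycaemia|diabetes-mellitus
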