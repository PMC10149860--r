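# Sample disease list: the ten conditions most often associated with
# UK digital-health publications. Load a full curated disease list with
# load_vocabulary() for real analyses.
Cerebrovascular Disease
Obesity
Asthma
Hypertension
Diabetes
Dementia
Myocardial Infarction
Coronary Artery Disease
Epilepsy
Schizophrenia
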