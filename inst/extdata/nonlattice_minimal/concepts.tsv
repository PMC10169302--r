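id	fsn	preferred_term	fully_defined	active
root	SNOMED CT concept (SNOMED RT+CTV3)	SNOMED CT concept	false	true
neoplasm_vulva	Neoplasm of vulva (disorder)	Neoplasm of vulva	true	true
disorder_bartholin	Disorder of Bartholin's gland (disorder)	Disorder of Bartholin's gland	true	true
benign_neoplasm_vulva	Benign neoplasm of vulva (disorder)	Benign neoplasm of vulva	false	true
malignant_tumor_vulva	Malignant tumor of vulva (disorder)	Malignant tumor of vulva	false	true
benign_neoplasm_bartholin	Benign neoplasm of Bartholin's gland (disorder)	Benign neoplasm of Bartholin's gland	false	true
malignant_neoplasm_bartholin	Malignant neoplasm of greater vestibular (Bartholin's) gland (disorder)	Malignant neoplasm of Bartholin's gland	false	true
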