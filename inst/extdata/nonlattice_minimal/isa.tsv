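child	parent
neoplasm_vulva	root
disorder_bartholin	root
benign_neoplasm_vulva	neoplasm_vulva
malignant_tumor_vulva	neoplasm_vulva
benign_neoplasm_bartholin	benign_neoplasm_vulva
benign_neoplasm_bartholin	disorder_bartholin
malignant_neoplasm_bartholin	malignant_tumor_vulva
malignant_neoplasm_bartholin	disorder_bartholin
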