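{"id": "20072857", "title": "Lung cysts following pulmonary artery operations: diagnostic and therapeutic implications", "abstract": "We review lung cysts observed after pulmonary artery operations."}
{"id": "30000001", "title": "Imaging of the fetal thoracic artery in the second trimester", "abstract": "The fetal thoracic artery was visualized in all cases."}
{"id": "30000002", "title": "A study of benign vulval neoplasms", "abstract": "Benign vulval neoplasms are uncommon in routine practice."}
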