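aui	cui	source	name
A24682086	C1853193	HPO	Cutaneous infections
A1639672	C0750998	MSH	Primary Cerebellar Neoplasm
A13728295	C0744147	MEDCIN	lesions feet
A9999001	C9999001	TEST	Severe cutaneous infections
A9999002	C9999002	TEST	Benign neoplasm of vulva
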