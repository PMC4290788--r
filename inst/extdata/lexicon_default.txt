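# Default decomposed subtype vocabulary.
# [SK] lines: variant<TAB>canonical subtype code; [AK]/[MK] lines: one variant.
# Matching is case-insensitive; variants are stored lowercased.

[SK]
papillary	PTC
anaplastic	ATC
undifferentiated	ATC
un-differentiated	ATC
follicular	FTC
medullary	MTC

[AK]
thyroid
thyroidal

[MK]
cancer
carcinoma
tumor
tumour
neoplasm
malignancy
malignant
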