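# Evidence-based primary-care abortive subset (Steiner et al., Aids to
# Management of Headache Disorders in Primary Care, 2nd ed.).
acetaminophen
aspirin
ibuprofen
naratriptan
diclofenac
eletriptan
frovatriptan
metoclopramide
sumatriptan
zolmitriptan
almotriptan
rizatriptan
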