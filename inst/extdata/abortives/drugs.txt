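# Headache abortive medications (non-opioid, non-barbiturate), one per line.
# Curated from the acute-therapy chapters of a standard headache handbook,
# plus the newer gepant/ditan abortives; mefenamic acid and rimegepant are
# absent because the interaction source had no data for them.
Ubrogepant
prochlorperazine
Tizanidine
Prednisone
Lasmiditan
Olanzapine
methylergonovine
Acetaminophen
Aspirin
Diflunisal
Fenoprofen
Ibuprofen
Ketoprofen
meclofenamate
Oxaprozin
Salsalate
Sulindac
Tolmetin
Etodolac
Flurbiprofen
Indomethacin
Ketorolac
Meloxicam
Naproxen
Piroxicam
Droperidol
Naratriptan
Diclofenac
Nabumetone
Celecoxib
dihydroergotamine
Eletriptan
Frovatriptan
Metoclopramide
Promethazine
Sumatriptan
Zolmitriptan
Almotriptan
Chlorpromazine
Rizatriptan
Ergotamine
Haloperidol
Dexamethasone
methylprednisolone
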