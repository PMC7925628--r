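drug_a	drug_b	description	severity
Sumatriptan	Ubrogepant	None
Sumatriptan	Prochlorperazine	The risk or severity of adverse effects can be increased when Sumatriptan is combined with Prochlorperazine
Sumatriptan	Tizanidine	The risk or severity of adverse effects can be increased when Sumatriptan is combined with Tizanidine
Sumatriptan	Prednisone	Prednisone may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Lasmiditan	The risk or severity of serotonin syndrome can be increased when Sumatriptan is combined with Lasmiditan
Sumatriptan	Olanzapine	Sumatriptan may increase the central nervous system depressant (CNS depressant) activities of Olanzapine
Sumatriptan	methylergonovine	may increase the vasoconstricting activities of Sumatriptan
Sumatriptan	Acetaminophen	Acetaminophen may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Aspirin	Acetylsalicylic acid may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Diflunisal	Diflunisal may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Fenoprofen	Fenoprofen may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Ibuprofen	Sumatriptan may decrease the excretion rate of Ibuprofen which could result in a higher serum level
Sumatriptan	Ketoprofen	The risk or severity of adverse effects can be increased when Ketoprofen is combined with Sumatriptan
Sumatriptan	meclofenamate	may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Oxaprozin	Oxaprozin may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Salsalate	Salsalate may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Sulindac	Sulindac may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Tolmetin	Tolmetin may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Etodolac	Etodolac may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Flurbiprofen	Flurbiprofen may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Indomethacin	Indomethacin may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Ketorolac	Ketorolac may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Meloxicam	Meloxicam may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Naproxen	None
Sumatriptan	Piroxicam	Piroxicam may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Droperidol	Droperidol may increase the central nervous system depressant (CNS depressant) activities of Sumatriptan
Sumatriptan	Naratriptan	The risk or severity of adverse effects can be increased when Sumatriptan is combined with Naratriptan
Sumatriptan	Diclofenac	Diclofenac may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Nabumetone	Nabumetone may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	Celecoxib	Celecoxib may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	dihydroergotamine	Dihydroergocristine may increase the vasoconstricting activities of Sumatriptan
Sumatriptan	Eletriptan	The risk or severity of adverse effects can be increased when Eletriptan is combined with Sumatriptan
Sumatriptan	Frovatriptan	The risk or severity of adverse effects can be increased when Sumatriptan is combined with Frovatriptan
Sumatriptan	Metoclopramide	The risk or severity of sedation can be increased when Sumatriptan is combined with Metoclopramide
Sumatriptan	Promethazine	Sumatriptan may increase the central nervous system depressant (CNS depressant) activities of Promethazine
Sumatriptan	Zolmitriptan	The risk or severity of vasospastic reactions can be increased when Zolmitriptan is combined with Sumatriptan
Sumatriptan	Almotriptan	The risk or severity of adverse effects can be increased when Sumatriptan is combined with Almotriptan
Sumatriptan	Chlorpromazine	Sumatriptan may increase the central nervous system depressant (CNS depressant) activities of Chlorpromazine
Sumatriptan	Rizatriptan	The risk or severity of adverse effects can be increased when Sumatriptan is combined with Rizatriptan
Sumatriptan	Ergotamine	Ergotamine may increase the vasoconstricting activities of Sumatriptan
Sumatriptan	Haloperidol	The risk or severity of CNS depression can be increased when Haloperidol is combined with Sumatriptan
Sumatriptan	Dexamethasone	Dexamethasone may decrease the excretion rate of Sumatriptan which could result in a higher serum level
Sumatriptan	methylprednisolone	Dexamethasone may decrease the excretion rate of Sumatriptan which could result in a higher serum level
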