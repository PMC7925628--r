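# Reference drug-class map. NSAID membership is the 20 universe drugs of
# that class; remaining labels are a pharmacological convenience.
aspirin	NSAID
celecoxib	NSAID
diclofenac	NSAID
diflunisal	NSAID
etodolac	NSAID
fenoprofen	NSAID
flurbiprofen	NSAID
ibuprofen	NSAID
indomethacin	NSAID
ketoprofen	NSAID
ketorolac	NSAID
meclofenamate	NSAID
meloxicam	NSAID
nabumetone	NSAID
naproxen	NSAID
oxaprozin	NSAID
piroxicam	NSAID
salsalate	NSAID
sulindac	NSAID
tolmetin	NSAID
ubrogepant	gepant
lasmiditan	ditan
sumatriptan	triptan
naratriptan	triptan
eletriptan	triptan
frovatriptan	triptan
zolmitriptan	triptan
almotriptan	triptan
rizatriptan	triptan
prochlorperazine	neuroleptic
chlorpromazine	neuroleptic
haloperidol	neuroleptic
olanzapine	neuroleptic
droperidol	neuroleptic
promethazine	neuroleptic
metoclopramide	antiemetic
prednisone	corticosteroid
dexamethasone	corticosteroid
methylprednisolone	corticosteroid
dihydroergotamine	ergot
ergotamine	ergot
methylergonovine	ergot
acetaminophen	analgesic
tizanidine	muscle relaxant
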