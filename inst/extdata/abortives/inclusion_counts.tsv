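# Reference per-drug inclusion counts: the number of interaction-free
# 2-4 drug combinations that contain each drug.
drug	count
ubrogepant	96
prochlorperazine	41
tizanidine	37
prednisone	31
lasmiditan	28
olanzapine	23
methylergonovine	17
acetaminophen	15
aspirin	8
diflunisal	8
fenoprofen	8
ibuprofen	8
ketoprofen	8
meclofenamate	8
oxaprozin	8
salsalate	8
sulindac	8
tolmetin	8
etodolac	6
flurbiprofen	6
indomethacin	6
ketorolac	6
meloxicam	6
naproxen	6
piroxicam	6
droperidol	5
naratriptan	5
diclofenac	4
nabumetone	4
celecoxib	3
dihydroergotamine	3
eletriptan	3
frovatriptan	3
metoclopramide	3
promethazine	3
sumatriptan	3
zolmitriptan	3
almotriptan	1
chlorpromazine	1
rizatriptan	1
ergotamine	0
haloperidol	0
dexamethasone	0
methylprednisolone	0
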