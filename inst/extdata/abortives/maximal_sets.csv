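# Condensed (maximal) interaction-free sets of abortive medications,
# one set per line, comma-joined drug names. Every 2-4 drug subset of a
# line is interaction-free; any pair not co-occurring on some line
# interacts. Line 74 (lasmiditan,ibuprofen) is retained as published even
# though it is a subset of line 16; strict condensation absorbs it.
acetaminophen,lasmiditan,methylergonovine,prednisone
ubrogepant,olanzapine,methylergonovine,prednisone
sulindac,ubrogepant,tizanidine
sulindac,ubrogepant,olanzapine
sulindac,ubrogepant,prochlorperazine
tolmetin,ubrogepant,tizanidine
tolmetin,ubrogepant,olanzapine
tolmetin,ubrogepant,prochlorperazine
aspirin,acetaminophen,lasmiditan
aspirin,ubrogepant,tizanidine
aspirin,ubrogepant,prochlorperazine
zolmitriptan,ubrogepant,prednisone
celecoxib,ubrogepant,tizanidine
naratriptan,acetaminophen,prednisone
naratriptan,ubrogepant,prednisone
acetaminophen,lasmiditan,ibuprofen
acetaminophen,droperidol,prednisone
ubrogepant,frovatriptan,prednisone
ubrogepant,eletriptan,prednisone
ubrogepant,etodolac,tizanidine
ubrogepant,etodolac,prochlorperazine
ubrogepant,nabumetone,prochlorperazine
ubrogepant,oxaprozin,tizanidine
ubrogepant,oxaprozin,olanzapine
ubrogepant,oxaprozin,prochlorperazine
ubrogepant,diclofenac,prochlorperazine
ubrogepant,diflunisal,tizanidine
ubrogepant,diflunisal,olanzapine
ubrogepant,diflunisal,prochlorperazine
ubrogepant,dihydroergotamine,prednisone
ubrogepant,ketorolac,tizanidine
ubrogepant,ketorolac,prochlorperazine
ubrogepant,salsalate,tizanidine
ubrogepant,salsalate,olanzapine
ubrogepant,salsalate,prochlorperazine
ubrogepant,droperidol,prednisone
ubrogepant,sumatriptan,naproxen
ubrogepant,meloxicam,tizanidine
ubrogepant,meloxicam,prochlorperazine
ubrogepant,fenoprofen,tizanidine
ubrogepant,fenoprofen,olanzapine
ubrogepant,fenoprofen,prochlorperazine
ubrogepant,flurbiprofen,tizanidine
ubrogepant,flurbiprofen,prochlorperazine
ubrogepant,ibuprofen,tizanidine
ubrogepant,ibuprofen,prochlorperazine
ubrogepant,tizanidine,indomethacin
ubrogepant,tizanidine,meclofenamate
ubrogepant,tizanidine,ketoprofen
ubrogepant,tizanidine,piroxicam
ubrogepant,tizanidine,prednisone
ubrogepant,indomethacin,prochlorperazine
ubrogepant,meclofenamate,olanzapine
ubrogepant,meclofenamate,prochlorperazine
ubrogepant,olanzapine,ketoprofen
ubrogepant,ketoprofen,prochlorperazine
ubrogepant,methylergonovine,metoclopramide
ubrogepant,methylergonovine,promethazine
ubrogepant,naproxen,prochlorperazine
ubrogepant,piroxicam,prochlorperazine
ubrogepant,prednisone,prochlorperazine
sulindac,lasmiditan
tolmetin,lasmiditan
lasmiditan,etodolac
lasmiditan,nabumetone
lasmiditan,oxaprozin
lasmiditan,diclofenac
lasmiditan,diflunisal
lasmiditan,ketorolac
lasmiditan,salsalate
lasmiditan,meloxicam
lasmiditan,fenoprofen
lasmiditan,flurbiprofen
lasmiditan,ibuprofen
lasmiditan,indomethacin
lasmiditan,meclofenamate
lasmiditan,ketoprofen
lasmiditan,naproxen
lasmiditan,piroxicam
ubrogepant,chlorpromazine
ubrogepant,almotriptan
ubrogepant,rizatriptan
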