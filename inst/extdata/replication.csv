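# Conceptual replication: 355 participants, four identification decisions
# each (two culprit-present and two culprit-absent six-person lineups),
# 1420 decisions in total.  fyc = first-yes-counts instructions; control =
# no first-yes-counts instructions.  Within each condition the
# culprit-present and culprit-absent tree totals are equal by design
# (fyc: 366/366, control: 344/344).
condition,lineup_type,outcome,count
fyc,culprit_present,suspect,112
fyc,culprit_present,filler,147
fyc,culprit_present,rejection,107
fyc,culprit_absent,suspect,31
fyc,culprit_absent,filler,184
fyc,culprit_absent,rejection,151
control,culprit_present,suspect,110
control,culprit_present,filler,167
control,culprit_present,rejection,67
control,culprit_absent,suspect,50
control,culprit_absent,filler,194
control,culprit_absent,rejection,100
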