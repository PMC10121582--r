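# Identification decisions of 559 participants in two sequential-lineup
# instruction conditions (one six-person lineup each), aggregated across
# suspect position.  fyc = first-yes-counts instructions; control = no
# first-yes-counts instructions.  Cell values validated against two
# independently published facts: the 559-decision total and the pooled
# lineup rejection rates 0.53 (fyc) / 0.43 (control).
condition,lineup_type,outcome,count
fyc,culprit_present,suspect,71
fyc,culprit_present,filler,26
fyc,culprit_present,rejection,61
fyc,culprit_absent,suspect,7
fyc,culprit_absent,filler,38
fyc,culprit_absent,rejection,102
control,culprit_present,suspect,69
control,culprit_present,filler,23
control,culprit_present,rejection,30
control,culprit_absent,suspect,5
control,culprit_absent,filler,48
control,culprit_absent,rejection,79
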