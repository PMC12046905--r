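variable,level,pn_neg,pn_pos
sex,male,236,81
sex,female,8,5
smoking,yes,226,78
smoking,no,18,8
alcohol,yes,170,61
alcohol,no,74,25
grade,Poor,34,26
grade,Moderate,117,38
grade,Well,93,22
tstage,T1,75,13
tstage,T2,88,23
tstage,T3,63,31
tstage,T4,18,19
enhancement,heterogeneous,57,32
enhancement,homogeneous,187,54
necrosis,yes,32,21
necrosis,no,212,65
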