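cohort,n,pn_pos
training,330,86
internal_test,154,48
external_test,183,61
genomic,50,15
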