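# Example pipeline configuration: simulate a full validation batch for the
# packaged method definition and validate it end to end.
method: method_fish.yaml
simulate: {}
seed: 7
c_ref_qc: 5
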