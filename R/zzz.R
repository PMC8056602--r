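# Let data.table's [ dispatch work inside this package's namespace.
.datatable.aware <- TRUE
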