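## data.table is used via :: throughout; mark the package data.table-aware
## so [.data.table keeps its semantics inside the namespace
.datatable.aware <- TRUE

utils::globalVariables(c(
    "kmer", "N", "seq.a", "seq.b", "pos.a", "pos.b", "d", "len",
    "matches", "identity", "orient", "qi", "spos", "start", "pos",
    "qname", "flag", "read", "transcript", "mismatches", "."
))
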