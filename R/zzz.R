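.datatable.aware <- TRUE

# quiet R CMD check notes for data.table non-standard evaluation columns
utils::globalVariables(c("ref_end", "cigar", "flag", "qname", "mate", "pos",
                         "rname", "tlen", ".N", "n", "nref"))
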