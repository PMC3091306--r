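.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".I", ".N", "entry", "new", "rep.", "si", "occ", "intensity", "mz",
  "acq", "scan."
))
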