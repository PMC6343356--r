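.onLoad <- function(libname, pkgname) {
  register_scorer("baseline", function(composite, fg_byte_threshold = 96)
    baseline_score(composite, fg_byte_threshold))
}
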