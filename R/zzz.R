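.onLoad <- function(libname, pkgname) {
  for (e in make_builtin_engines()) register_engine(e)
  invisible()
}
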