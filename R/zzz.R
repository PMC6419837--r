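.onLoad <- function(libname, pkgname) {
  # OpenBabel prints a C-level warning to stderr for every unparseable
  # SMILES; invalid strings are expected, classified inputs here (untrained
  # models emit mostly invalid sequences), so silence the handler.
  tryCatch({
    ns <- getNamespace("ChemmineOB")
    ns$OBMessageHandler_StopLogging(ns$obErrorLog_get())
  }, error = function(e) invisible(NULL))
  invisible(NULL)
}
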