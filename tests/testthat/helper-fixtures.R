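# Fresh scratch directory, removed when the calling test completes.
withr_local_tempdir <- function(env = parent.frame()) {
  dir <- tempfile("elascape-test-")
  dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}
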