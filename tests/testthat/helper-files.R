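# Write literal file content (exact bytes) under tempdir() and return the path.
local_file <- function(name, content) {
  path <- file.path(tempdir(), name)
  cat(content, file = path)
  path
}
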