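## Shared fixtures: the default parameter set calibrated against the shipped
## anchors, cached once per test run.
calibrated_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_parameters(default_parameters())
    cache
  }
})

default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "silicaCBA")
}

## Write a modified copy of the default raw config and return its path
write_modified_config <- function(modify) {
  raw <- yaml::read_yaml(default_config_path())
  raw <- modify(raw)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path, precision = 15)
  path
}
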