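# Shared fixtures.  Impact runs are expensive, so the default-scenario runs
# used by several acceptance checks are computed once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

impact_fixture <- function(target = 1250) {
  key <- paste0("impact_", target)
  if (!exists(key, envir = .fixture_env)) {
    cfg <- impact_config(geometry = geometry_spec(target_element_count = target))
    assign(key, run_impact(cfg), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

tiny_impact_config <- function(...) {
  impact_config(geometry = geometry_spec(target_element_count = 600),
                duration = 1.2, output_every = 0.02, ...)
}

single_element_model <- function(material, size_mm = 1) {
  mesh <- make_block_mesh(1, 1, c(0, size_mm), c(0, size_mm),
                          region = "specimen", material = material$name)
  assemble_model(mesh, stats::setNames(list(material), material$name))
}
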