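# Memoized preset runs shared by the scenario-level tests (each full
# scenario takes a few minutes; run each preset once per test session).
.preset_runs <- new.env(parent = emptyenv())

preset_run <- function(name) {
  if (is.null(.preset_runs[[name]])) {
    t0 <- Sys.time()
    res <- run_simulation(preset_config(name))
    attr(res, "elapsed_s") <- as.numeric(Sys.time() - t0, units = "secs")
    .preset_runs[[name]] <- res
  }
  .preset_runs[[name]]
}
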