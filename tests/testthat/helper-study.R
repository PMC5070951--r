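# Shared scaled-down study fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tiny_config <- function(...) {
  defaults <- list(n_subjects = 4, n_loads = 2, n_trials_per_load = 10,
                   n_parcels = 4, n_coarse = 4, sampling_rate = 300,
                   snr = 2, mixing_width = 0, pad = 0.55, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(study_config, args)
}

# A small study with one planted retention-only CFS edge 1 -> 3 at
# 10 Hz, ratio 1:3.
cfs_fixture <- function() {
  fixture("cfs_study", function() {
    generate_study(tiny_config(seed = 21),
                   list(coupling_spec(1, 3, 10, 3, 0.8, "cfs")))
  })
}
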