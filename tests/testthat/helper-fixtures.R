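# Shared simulation fixtures, built once per test run and cached.
# Seeds are fixed arbitrary constants; the simulations use the
# package's default (stated-world) parameters throughout.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

default_optics <- function() fixture("optics", function() optics_model())

default_cfg <- function() localizer_config()

default_tables <- function() fixture("tables", function()
  localizer_tables(default_cfg(), default_optics()))

# 39 long static-emitter traces (the paper-scale single-molecule set)
static_traces <- function() fixture("static_traces", function() {
  simulate_static_traces(n_traces = 39, photons_after_nc = 10000,
                         cfg = default_cfg(), optics = default_optics(),
                         seed = 20260901)
})

static_precision <- function() fixture("static_precision", function() {
  precision_summary(static_traces(), N_eval = c(400, 2000, 10000))
})

# repeated-binding origami experiment: 3 grids, 240 s, jitter 0.72 nm
origami_experiment <- function() fixture("origami_experiment", function() {
  simulate_origami_experiment(n_origami = 3, spacing = 12,
                              duration_s = 240,
                              cfg = default_cfg(),
                              optics = default_optics(),
                              seed = 20260902)
})

# convergence-filtered traces of the origami experiment, plus the
# cluster assignment of their final positions
origami_filtered <- function() fixture("origami_filtered", function() {
  ex <- origami_experiment()
  pc <- precision_config()
  keep <- vapply(ex$traces, function(tr)
    tr$initiated && isTRUE(convergence_filter(tr, pc)), logical(1))
  traces <- ex$traces[keep]
  locs <- localization_table(traces, pc)
  clusters <- cluster_localizations(locs[, c("x_nm", "y_nm")], pc)
  list(traces = traces[locs$id], locs = locs, clusters = clusters,
       site_of = ex$site_of[keep][locs$id])
})
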