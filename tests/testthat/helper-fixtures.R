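# Shared fixtures.  Heavy objects are built lazily and cached for the
# whole test run; everything is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, builder(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

fix_default_params <- function() cached("default", default_parameters)

fix_synth_params <- function(seed = 1, profile = "default") {
  cached(paste0("synth_", profile, "_", seed),
         function() generate_nominal_parameters(seed = seed,
                                                profile = profile))
}

fix_healthy <- function(params, key) {
  cached(paste0("healthy_", key), function() healthy_steady_state(params))
}

# the three hormone-condition ensembles of the scaled-down comparison
# (200 samples per condition, +/-20% coefficient variation, daily output)
fix_condition_ensembles <- function(n = 200) {
  cached(paste0("cond_", n), function() {
    p <- fix_default_params()
    conds <- c(male = 101L, female_low_e = 102L, female_peak_e = 103L)
    out <- lapply(names(conds), function(cn)
      run_condition(p, cn, n = n, seed = conds[[cn]], t_end = 480,
                    grid = 24))
    names(out) <- names(conds)
    out
  })
}
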