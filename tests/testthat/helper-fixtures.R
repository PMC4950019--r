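# Fast model configurations for unit tests (small coupling keeps the
# sub-step count low; physics-accurate values are exercised in
# test-acceptance.R via the package defaults).
fast_params <- function(engine = "cpp") {
  erasim_params(fill = fill_params(decay = 1, couple = 50, block = 200),
                engine = engine)
}

random_opponent <- function(h, w) {
  s <- matrix(stats::runif(h * w, -0.4, 0.4), h, w)
  structure(list(on = pmax(s, 0), off = pmax(-s, 0)),
            class = "opponent_field")
}

random_perm <- function(h, w, params) {
  b <- structure(list(vertical = matrix(stats::runif(h * w, 0, 1), h, w),
                      horizontal = matrix(stats::runif(h * w, 0, 1), h, w)),
                 class = "boundary_field")
  permeability(b, params)
}

# memoised battery runs shared across acceptance tests
.battery_cache <- new.env(parent = emptyenv())
cached_battery <- function(battery_id) {
  if (is.null(.battery_cache[[battery_id]]))
    .battery_cache[[battery_id]] <- run_experiment_battery(battery_id)
  .battery_cache[[battery_id]]
}
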