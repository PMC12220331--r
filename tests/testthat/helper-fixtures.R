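# shared fixtures, built in code and cached for the test run

small_grid <- function(dims = c(24, 28, 24)) {
  volume_grid(dims, c(2, 2, 2))
}

small_cfg <- function(seed = 42, n_controls = 8, n_patients = 6, ...) {
  sim_config(seed = seed, n_controls = n_controls,
             n_patients = n_patients, grid = small_grid(), ...)
}

.fixture_env <- new.env()

# one small simulated cohort reused across test files
fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(small_cfg())
  }
  .fixture_env$cohort
}

fixture_atlas <- function() {
  if (is.null(.fixture_env$atlas)) {
    .fixture_env$atlas <- build_atlas_phantom(small_grid())
  }
  .fixture_env$atlas
}

# random in-brain volume on a grid, for oracle tests
random_volume <- function(grid, seed, mean = 100, sd = 10) {
  withr::with_seed(seed, {
    brain_volume(array(stats::rnorm(prod(grid$dims), mean, sd),
                       dim = grid$dims), grid)
  })
}

full_mask <- function(grid) {
  region_mask(array(TRUE, grid$dims), grid, "full")
}

# hand-built activation map for ROI tests
make_activation <- function(active, grid, limb = "upper", side = "L") {
  structure(list(active = array(as.logical(active), grid$dims),
                 grid = grid, limb = limb, side = side),
            class = "activation_map")
}
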