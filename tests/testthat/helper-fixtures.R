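# shared fixtures, built once per test run and memoised
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

coarse_mesh <- function() fixture("coarse_mesh", function() build_mesh(47.5, 0))
prod_mesh <- function() fixture("prod_mesh", function() build_mesh(47.5, 1))
std_protocol <- function() fixture("protocol", function() adjacent_protocol())
std_grid <- function() fixture("grid", function() recon_grid())

homog_sigma <- function(mesh, value = 5.5e-4) rep(value, nrow(mesh$elements))

# small dataset on the coarse mesh: 60 samples, 48/12 split
small_dataset <- function() {
  fixture("small_dataset", function() {
    generate_dataset(n_samples = 60, mesh = coarse_mesh(),
                     protocol = std_protocol(), grid = std_grid(),
                     train_fraction = 48 / 60, rng_seed = 42)
  })
}

# voltage for one drive/measurement electrode pair combination
pair_voltage <- function(mesh, sigma, drive, meas, amplitude = 5e-4) {
  U <- solve_fields(mesh, sigma, matrix(drive, ncol = 2), amplitude)
  E <- electrode_voltages(mesh, U)
  E[meas[1], 1] - E[meas[2], 1]
}
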