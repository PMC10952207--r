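# Shared fixtures, built once per test run and memoized. Everything is
# generated in code at test time; sizes are kept small (coarse grids) so the
# whole suite stays inside its runtime budget.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small built-in subject phantom (5 mm grid) + its fields and Q set
fx_model <- function() fixture("model", function() {
  make_phantom(builtin_phantom_specs()$subject1, voxel_size = 5)
})

fx_fields <- function() fixture("fields", function() {
  simulate_channel_fields(coil_model(), fx_model())
})

fx_qset <- function() fixture("qset", function() {
  build_q_matrices(fx_fields(), fx_model())
})

# tiny uniform-density cube phantom: single tissue, handy for closed forms
fx_uniform_model <- function(n = 14, voxel = 2, density = 1000) {
  tt <- default_tissue_table()
  tt$density_kg_per_m3[tt$name == "muscle"] <- density
  lab <- array(tt$label[tt$name == "muscle"], rep(n, 3))
  voxel_model(lab, voxel, tt)
}
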