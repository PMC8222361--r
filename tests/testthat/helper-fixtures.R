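# Shared fixtures, built once per test run. The "small" phantom keeps the
# full structure (all five materials, fenestrations, both tooth types,
# symmetric landmarks) at a size where an FE solve takes a couple of
# seconds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_params <- function() {
  phantom_params(length = 40, height = 10, crown_height = 3,
                 n_cheek_teeth = 1, n_fenestrations = 2)
}

small_phantom <- function() {
  fixture("small_phantom", function() make_cranium_phantom(small_params()))
}

small_jaw <- function() {
  fixture("small_jaw", function() build_jaw_model(small_params()))
}

small_system <- function() {
  fixture("small_system", function() assemble_system(small_phantom()))
}

# right-side molar regime on the small phantom and its reflection
small_regimes <- function() {
  fixture("small_regimes", function() {
    traj <- simulate_bite_cycle(
      small_jaw(), bite_cycle_spec("molar", tooth = "cheek1", side = "R",
                                   dt = 0.01))
    r <- extract_load_regime(traj)
    list(R = r, L = reflect_load_regime(r))
  })
}

small_fields <- function() {
  fixture("small_fields", function() {
    regs <- small_regimes()
    lapply(regs, function(r)
      run_load_case(small_phantom(), regime = r, system = small_system()))
  })
}

# a synthetic peak-strain-like setup for aggregation oracles: random
# strain fields on a tiny mesh, fixed seed
synthetic_fields <- function(n_fields = 4, seed = 42) {
  mesh <- make_unit_cube_mesh(3)
  set.seed(seed)
  fields <- lapply(seq_len(n_fields), function(i) {
    ne <- nrow(mesh$elems)
    pr <- cbind(stats::runif(ne, 0, 800), stats::runif(ne, -200, 200),
                stats::runif(ne, -900, 0))
    pr <- t(apply(pr, 1, sort, decreasing = TRUE))
    structure(list(tensor = matrix(0, ne, 6), principal = pr,
                   vm = stats::runif(ne, 0, 1200),
                   regime_id = paste0("case", i)),
              class = "strain_field")
  })
  list(mesh = mesh, fields = fields)
}
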