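test_that("LJ energy at the minimum distance equals minus the well depth", {
  spec <- energy_spec(bonded = FALSE) # chargeless HETATM pair -> LJ only
  rmin <- 2 * spec$lj_rmin2[["C"]]
  s <- pair_structure(rmin)
  expect_equal(evaluate_energy(s, spec), -spec$lj_eps[["C"]],
               tolerance = 1e-12)
})

test_that("Coulomb term matches the closed form under the 4r dielectric", {
  spec <- energy_spec(lj_scale = 0, bonded = FALSE,
                      substrate_charges = c(Q1 = 0.5, Q2 = -0.5))
  s <- pair_structure(3.0)
  # 332.0636 * (0.5 * -0.5) / (4 * 3^2), hand-evaluated
  expect_equal(evaluate_energy(s, spec), -2.30599722222222,
               tolerance = 1e-9)
  # constant-dielectric variant: k q1 q2 / (eps r)
  spec2 <- energy_spec(lj_scale = 0, bonded = FALSE, dielectric = "constant",
                       eps_const = 4, substrate_charges = c(Q1 = 0.5, Q2 = -0.5))
  expect_equal(evaluate_energy(s, spec2), 332.0636 * -0.25 / (4 * 3),
               tolerance = 1e-9)
})

test_that("energy is invariant under rigid motion and atom reordering", {
  toy <- toy20
  spec <- energy_spec()
  e0 <- evaluate_energy(toy, spec)
  set.seed(44)
  for (k in 1:5) {
    R <- ensdesign:::random_rotation()
    moved <- new_structure(toy$atoms,
                           sweep(toy$xyz %*% t(R), 2L, rnorm(3, sd = 20), "+"))
    expect_lt(abs(evaluate_energy(moved, spec) - e0), 1e-8)
  }
  perm <- sample(nrow(toy$atoms))
  a <- toy$atoms[perm, ]; a$serial <- seq_along(perm)
  shuffled <- new_structure(a, toy$xyz[perm, ])
  expect_lt(abs(evaluate_energy(shuffled, spec) - e0), 1e-8)
})

test_that("overlapping atoms raise an overlap error", {
  s <- pair_structure(0.05)
  expect_error(evaluate_energy(s), "overlap")
})

test_that("a stretched harmonic bond relaxes to its reference length", {
  spec <- energy_spec(lj_scale = 0, k_bond = 300)
  ref <- pair_structure(1.5)   # bonded at 1.5 A in the reference
  x <- pair_structure(1.8)     # stretched by 0.3
  topo <- energy_topology(x, spec, reference = ref)
  expect_equal(nrow(topo$harm), 1L)
  res <- minimize_state(x, spec, max_iter = 2000L, grad_tol = 1e-5,
                        topo = topo)
  d <- sqrt(sum((res$structure$xyz[1L, ] - res$structure$xyz[2L, ])^2))
  expect_lt(abs(d - 1.5), 1e-4)
  expect_lt(res$energy, 1e-6)
  expect_true(res$converged)

  # already-minimized input: no iterations, energy unchanged
  again <- minimize_state(res$structure, spec, grad_tol = 1e-3,
                          topo = energy_topology(res$structure, spec,
                                                 reference = ref))
  expect_lte(again$iterations, 1L)
  expect_equal(again$energy, res$energy, tolerance = 1e-6)
})

test_that("minimization traces are monotone non-increasing", {
  prot <- protein_only(toy20)
  tmpl <- make_substrate_templates(toy20)
  for (st in c("ES", "ES_STAR")) {
    state <- build_state(prot, tmpl[[if (st == "ES") "ES" else "ES_STAR"]], st)
    res <- minimize_state(state, max_iter = 120L, grad_tol = 0.05)
    expect_true(all(diff(res$trace) <= 1e-9))
    expect_lte(res$energy, res$initial_energy)
  }
})

test_that("complex states carry the tetrahedral-intermediate restraint", {
  prot <- protein_only(toy20)
  tmpl <- make_substrate_templates(toy20)
  es <- build_state(prot, tmpl$ES, "ES")
  expect_null(es$restraint)
  star <- build_state(prot, tmpl$ES_STAR, "ES_STAR")
  expect_equal(star$restraint$target, 1.9)

  # restraint dominates: minimized Ser Ogamma - carbonyl C near target
  res <- minimize_state(star, max_iter = 300L, grad_tol = 0.02)
  d <- sqrt(sum((res$structure$xyz[star$restraint$i, ] -
                   res$structure$xyz[star$restraint$j, ])^2))
  expect_lt(abs(d - 1.9), 0.05)

  # collinear anchor frame is rejected
  bad <- tmpl$ES
  bad$ref_coords <- cbind(1:3, 0, 0)
  expect_error(build_state(prot, bad, "ES"), "collinear")
})

test_that("a constant ES* bias shifts frozen-geometry energy differences exactly", {
  toy <- toy20
  ens <- new_ensemble(list(toy, toy, toy))
  tmpl <- make_substrate_templates(toy)
  base <- delta_e_ensemble(ens, tmpl, variant = "WT", max_iter = 0L)
  biased <- delta_e_ensemble(ens, tmpl, variant = "b", max_iter = 0L,
                             es_star_bias = 1.75)
  expect_equal(biased$delta_e, base$delta_e + 1.75, tolerance = 1e-6)
})
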