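test_that("geometric criteria: distance and angle must both hold", {
  crit <- hbond_criteria()
  expect_true(detect_hbond(dha_frame(2.9, 160), dha_defn, crit))
  expect_false(detect_hbond(dha_frame(3.1, 170), dha_defn, crit))
  expect_false(detect_hbond(dha_frame(2.8, 140), dha_defn, crit))
  # boundary: <= 3.0 and >= 150 are inclusive
  expect_true(detect_hbond(dha_frame(2.9999, 150.01), dha_defn, crit))
  # missing atoms are named in the error
  bad <- hbond_definition(9L, donor = atom_spec(1L, "ZZ", "A"),
                          acceptor = atom_spec(1L, "O", "X"))
  expect_error(detect_hbond(dha_frame(2.9, 160), bad), "ZZ")
})

test_that("occupancy counts frames; joint never exceeds marginals", {
  gen <- make_hbond_frames(target_occ = c(40, 100), n_frames = 100L,
                           rng_seed = 2L)
  occ <- hbond_occupancy(gen$ensemble, gen$defns)
  f <- setNames(occ$frequency_pct, occ$bond)
  expect_equal(unname(f["hbond_1"]), gen$ground_truth$realized_occ$hbond_1)
  expect_equal(unname(f["hbond_2"]), 100)
  expect_lte(f[["all"]], min(f[["hbond_1"]], f[["hbond_2"]]))

  # disjoint bonds: all-four 0% while min individual is 50%
  mk <- function(on1) {
    a <- dha_frame(if (on1) 2.8 else 4.5, 165)$atoms
    x <- dha_frame(if (on1) 2.8 else 4.5, 165)$xyz
    b <- dha_frame(if (on1) 4.5 else 2.8, 165)
    b$atoms$res_id <- 2L
    xx <- sweep(b$xyz, 2L, c(20, 0, 0), "+")
    at <- rbind(a, b$atoms); at$serial <- 1:6
    new_structure(at, rbind(x, xx))
  }
  frames <- new_ensemble(c(replicate(50, mk(TRUE), simplify = FALSE),
                           replicate(50, mk(FALSE), simplify = FALSE)))
  defns <- list(dha_defn,
                hbond_definition(2L, donor = atom_spec(2L, "N", "A"),
                                 acceptor = atom_spec(2L, "O", "X"),
                                 hydrogen = atom_spec(2L, "H", "A")))
  occ2 <- hbond_occupancy(frames, defns)
  expect_equal(occ2$frequency_pct, c(50, 50, 0))
})

test_that("idealized-hydrogen fallback handles hydrogen-free backbones", {
  # toy enzyme has no hydrogens; fallback must still evaluate without error
  defns <- canonical_hbonds(oxyanion_res = c(8L, 9L), ser = 7L, his = 14L,
                            asp = 19L)
  crit <- hbond_criteria(fallback = "ideal_h")
  for (d in defns)
    expect_type(detect_hbond(toy20, d, crit), "logical")
  # distance-only mode accepts any angle
  wide <- dha_frame(2.9, 100)
  wide <- new_structure(wide$atoms[-2L, ], wide$xyz[-2L, ])
  d2 <- hbond_definition(1L, donor = atom_spec(1L, "N", "A"),
                         acceptor = atom_spec(1L, "O", "X"))
  expect_true(detect_hbond(wide, d2,
                           hbond_criteria(fallback = "distance_only")))
})

test_that("threshold scan is monotone in distance-only mode", {
  gen <- make_hbond_frames(target_occ = c(30, 60, 90, 50), n_frames = 80L,
                           rng_seed = 5L)
  scan <- threshold_scan(gen$ensemble, gen$defns,
                         distances = c(2.5, 3.0, 3.5, 4.0, 5.0))
  for (b in unique(scan$bond)) {
    freq <- scan$frequency_pct[scan$bond == b]
    expect_true(all(diff(freq) >= 0))
  }
  # the 4.5 A violating pose turns on beyond its distance
  b1 <- scan$frequency_pct[scan$bond == "hbond_1"]
  expect_equal(b1[length(b1)], 100)

  one <- threshold_scan(gen$ensemble, gen$defns, distances = 3.0,
                        crit = hbond_criteria())
  direct <- hbond_occupancy(gen$ensemble, gen$defns, hbond_criteria())
  expect_equal(one$frequency_pct, direct$frequency_pct)

  expect_error(threshold_scan(gen$ensemble, gen$defns, c(3.0, 2.5)),
               "sorted")
})

test_that("association handles monotone, constant and grouped activity", {
  variants <- paste0("V", 1:8)
  occ <- data.frame(variant = variants, step = "TI1", bond = "hbond_1",
                    frequency_pct = seq(10, 80, by = 10))
  act <- data.frame(variant = variants, activity = seq(5, 600, length.out = 8))
  res <- activity_association(occ, act, n_perm = 500L, rng_seed = 1L)
  expect_equal(res$rho, 1.0)
  expect_lt(res$p_perm, 0.05)

  const <- occ; const$frequency_pct <- 50
  res2 <- activity_association(const, act, n_perm = 100L)
  expect_equal(res2$rho, 0)
  expect_true(res2$degenerate)

  act3 <- data.frame(variant = variants,
                     activity = c(0, 0, 0, 0, 120, 300, 450, 932))
  res3 <- activity_association(occ, act3, n_perm = 200L, rng_seed = 2L)
  expect_false(is.na(res3$rank_sum_p))
  act4 <- data.frame(variant = variants, activity = c(0, rep(100, 7)))
  res4 <- activity_association(occ, act4, n_perm = 200L, rng_seed = 2L)
  expect_match(res4$group_flag, "group-size")
  expect_false(is.na(res4$rho))
})

test_that("permutation p-values are uniform under the null", {
  set.seed(99)
  n_null <- 200L
  pv <- numeric(n_null)
  variants <- paste0("V", 1:10)
  for (k in seq_len(n_null)) {
    occ <- data.frame(variant = variants, step = "s", bond = "b",
                      frequency_pct = rnorm(10))
    act <- data.frame(variant = variants, activity = rnorm(10))
    pv[k] <- activity_association(occ, act, n_perm = 400L,
                                  rng_seed = k)$p_perm
  }
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})
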