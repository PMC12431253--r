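test_that("toy enzyme construction is deterministic and carries its metadata", {
  t1 <- make_toy_enzyme(20L, rng_seed = 4L)
  t2 <- make_toy_enzyme(20L, rng_seed = 4L)
  expect_identical(t1$xyz, t2$xyz)
  t3 <- make_toy_enzyme(20L, rng_seed = 5L)
  expect_false(identical(t1$xyz, t3$xyz))

  meta <- attr(t1, "meta")
  expect_length(meta$triad, 3L)
  expect_equal(unique(t1$atoms$res_name[t1$atoms$res_id == meta$ser &
                                          !t1$atoms$het]), "SER")
  expect_equal(unique(t1$atoms$res_name[t1$atoms$res_id == meta$his &
                                          !t1$atoms$het]), "HIS")
  expect_equal(unique(t1$atoms$res_name[t1$atoms$res_id == meta$asp &
                                          !t1$atoms$het]), "ASP")
  expect_equal(sum(t1$atoms$het), 6L) # one substrate fragment
  expect_error(make_toy_enzyme(5L), "config error")

  # docked pose: carbonyl carbon 2.9 A from the serine hydroxyl oxygen
  og <- t1$xyz[t1$atoms$res_id == meta$ser & t1$atoms$name == "OG", ]
  c1 <- t1$xyz[t1$atoms$het & t1$atoms$name == "C1", ]
  expect_equal(sqrt(sum((og - c1)^2)), 2.9, tolerance = 1e-9)
})

test_that("flexibility generator hits its RMSF target", {
  quiet <- make_flex_ensemble(toy20, per_res_sigma = 0, n_frames = 5L,
                              rng_seed = 1L)
  expect_true(all(rmsf_profile(quiet$ensemble, fit = FALSE)$rmsf == 0))

  sig <- setNames(1.0, "10")
  gen <- make_flex_ensemble(toy20, per_res_sigma = sig, n_frames = 2000L,
                            rng_seed = 2L)
  prof <- rmsf_profile(gen$ensemble, fit = FALSE)
  measured <- prof$rmsf[prof$res_id == 10L]
  expect_lt(abs(measured - sqrt(3)) / sqrt(3), 0.05)
  expect_true(all(prof$rmsf[prof$res_id != 10L] == 0))
  expect_equal(gen$ground_truth$expected_rmsf[["A 10"]], sqrt(3))

  expect_error(make_flex_ensemble(toy20, 0.5, n_frames = 1L), ">= 2")
  # protocol-sized ensemble
  expect_length(make_flex_ensemble(toy20, 0.2, n_frames = 96L,
                                   rng_seed = 1L)$ensemble$members, 96L)
})

test_that("planted effects behave as stated in the degenerate cases", {
  flat <- plant_variant_effects(c(WT = 0, V1 = 0, V2 = 0), noise_sigma = 0,
                                n_frames = 10L, rng_seed = 1L)
  for (tb in flat$variants)
    expect_equal(as.numeric(normalize_median(tb, flat$wt)), 1.0)

  down <- plant_variant_effects(c(WT = 0, V1 = -1), noise_sigma = 0,
                                n_frames = 10L, rng_seed = 1L)
  expect_lt(as.numeric(normalize_median(down$variants$V1, down$wt)), 1)

  expect_error(plant_variant_effects(c(V1 = -1)), "wild type")
  expect_error(plant_variant_effects(c(WT = 0.5, V1 = -1)), "must be 0")
})

test_that("hydrogen-bond frame generator is reproducible and on target", {
  g1 <- make_hbond_frames(c(100, 0), n_frames = 50L, rng_seed = 3L)
  occ <- hbond_occupancy(g1$ensemble, g1$defns)
  expect_equal(occ$frequency_pct[1L], 100)
  expect_equal(occ$frequency_pct[2L], 0)

  g2 <- make_hbond_frames(c(40, 70), n_frames = 100L, rng_seed = 4L)
  g3 <- make_hbond_frames(c(40, 70), n_frames = 100L, rng_seed = 4L)
  occ2 <- hbond_occupancy(g2$ensemble, g2$defns)
  occ3 <- hbond_occupancy(g3$ensemble, g3$defns)
  expect_identical(occ2, occ3)
  expect_equal(occ2$frequency_pct[1L], g2$ground_truth$realized_occ$hbond_1)

  joint <- make_hbond_frames(c(50, 50), n_frames = 200L, rng_seed = 5L,
                             joint_mode = "joint")
  oj <- hbond_occupancy(joint$ensemble, joint$defns)
  expect_equal(oj$frequency_pct[1L], oj$frequency_pct[3L]) # all == marginal
  expect_error(make_hbond_frames(c(120, 50)), "\\[0, 100\\]")
})

test_that("MSA generator respects conservation levels and seeds", {
  full <- make_msa(length = 5L, n_seqs = 30L, conservation = 1, rng_seed = 6L)
  expect_true(all(apply(full$msa$ali, 2L, function(col)
    length(unique(col)) == 1L)))

  m1 <- make_msa(length = 8L, n_seqs = 10L, conservation = 0.5, rng_seed = 7L)
  m2 <- make_msa(length = 8L, n_seqs = 10L, conservation = 0.5, rng_seed = 7L)
  expect_identical(m1$msa$ali, m2$msa$ali)

  # conservation at the background rate gives near-zero scores at large n
  bg <- make_msa(length = 4L, n_seqs = 4000L, conservation = 0.05,
                 rng_seed = 8L)
  p <- compute_pssm(bg$msa)
  expect_lt(max(abs(p$scores)), 0.6)
  expect_error(make_msa(5L, 1L, 0.5), ">= 2")
})

test_that("ground-truth sidecars serialize to JSON", {
  gen <- make_hbond_frames(c(30, 60), n_frames = 20L, rng_seed = 9L)
  tf <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gen$ground_truth, tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back$generator, "make_hbond_frames")
  expect_equal(back$n_frames, 20L)
})
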