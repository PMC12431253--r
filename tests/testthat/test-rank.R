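mk_table <- function(delta_e, variant = "v") {
  ensdesign:::delta_e_table(variant, rep(0, length(delta_e)), delta_e)
}

test_that("normalization: identity gives exactly 1, medians resist outliers", {
  wt <- mk_table(c(8, 9, 10, 11, 12), "WT")
  expect_identical(as.numeric(normalize_median(wt, wt)), 1)

  # ratios {0.9 x5, 10} -> median 0.9 (outlier-robust)
  wt6 <- mk_table(c(8, 9, 10, 11, 12, 10), "WT")
  mut6 <- mk_table(c(8, 9, 10, 11, 12, 10) * c(rep(0.9, 5), 10))
  expect_equal(as.numeric(normalize_median(mut6, wt6)), 0.9)

  # proportional tables agree in both modes
  mut2 <- mk_table(0.9 * wt$delta_e)
  expect_equal(as.numeric(normalize_median(mut2, wt, "per_frame_ratio")), 0.9)
  expect_equal(as.numeric(normalize_median(mut2, wt, "median_of_medians")), 0.9)

  # scale invariance under c > 0
  for (c_ in c(0.2, 3, 40)) {
    expect_equal(as.numeric(normalize_median(mk_table(c_ * mut2$delta_e),
                                             mk_table(c_ * wt$delta_e))),
                 0.9, tolerance = 1e-12)
  }
  expect_error(normalize_median(mk_table(c(1, 1)), mk_table(c(0, 0))),
               "normalization undefined")
})

test_that("the three filters are strict and monotone in their thresholds", {
  cand <- data.frame(
    name = c("pass_all", "fail_energy", "fail_pssm_exact", "fail_dist",
             "boundary_energy"),
    delta_e_norm = c(0.98, 0.99, 0.98, 0.98, 0.985),
    pssm_score = c(-3.0, -3.0, -4.0, -3.0, -3.0),
    min_substrate_distance = c(4.5, 4.5, 4.5, 5.0, 4.5))
  out <- apply_filters(cand)
  flags <- setNames(out$passes, out$name)
  expect_true(flags[["pass_all"]])
  expect_false(flags[["fail_energy"]])        # 0.99 >= 0.985
  expect_false(flags[["fail_pssm_exact"]])    # -4.0 is not > -4.0
  expect_false(flags[["fail_dist"]])          # 5.0 is not < 5.0
  expect_false(flags[["boundary_energy"]])    # 0.985 is not < 0.985

  expect_equal(sort(out$rank), seq_len(nrow(out)))
  # three candidates tie at 0.98: ranks follow lexicographic name order
  tied <- out$name[out$rank <= 3L]
  expect_equal(tied, sort(c("pass_all", "fail_pssm_exact", "fail_dist")))

  relaxed <- apply_filters(cand, list(delta_e = 1.1, pssm = -5, distance = 6))
  expect_true(all(relaxed$passes[match(out$name[out$passes], relaxed$name)]))
  expect_true(sum(relaxed$passes) >= sum(out$passes))

  expect_error(apply_filters(cand[, -2L]), "incomplete candidate")
})

test_that("noiseless planted offsets are recovered in exact order", {
  deltas <- c(WT = 0, D = 1.5, A = -2, C = 0.5, B = -1)
  pl <- plant_variant_effects(deltas, noise_sigma = 0, n_frames = 24L,
                              rng_seed = 5L)
  for (mode in c("per_frame_ratio", "median_of_medians")) {
    den <- vapply(pl$variants, function(tb)
      as.numeric(normalize_median(tb, pl$wt, mode)), numeric(1L))
    expect_equal(names(sort(den)), c("A", "B", "C", "D"))
  }
})

test_that("stability: identical conditions give rho 1, reversal gives -1", {
  pl <- plant_variant_effects(c(WT = 0, V1 = -2, V2 = -1, V3 = 0, V4 = 1),
                              noise_sigma = 0, n_frames = 20L, rng_seed = 2L)
  same <- list(a = list(wt = pl$wt, variants = pl$variants),
               b = list(wt = pl$wt, variants = pl$variants))
  st <- rank_stability(same, n_subsamples = 0L, rng_seed = 1L)
  expect_equal(unname(st$rho), matrix(1, 2L, 2L))
  expect_equal(st$mean_topk, 1)

  rev_pl <- plant_variant_effects(c(WT = 0, V1 = 1, V2 = 0.5, V3 = 0,
                                    V4 = -0.5),
                                  noise_sigma = 0, n_frames = 20L,
                                  rng_seed = 2L)
  flip <- list(a = list(wt = pl$wt, variants = pl$variants),
               b = list(wt = rev_pl$wt, variants = rev_pl$variants))
  st2 <- rank_stability(flip, n_subsamples = 0L, rng_seed = 1L)
  expect_equal(st2$rho[1L, 2L], -1)

  expect_error(rank_stability(list(wt = pl$wt,
                                   variants = pl$variants[1:2]),
                              n_subsamples = 2L, subsample_frames = 5L),
               "insufficient variants")
})

test_that("stability subsampling is deterministic per seed", {
  pl <- plant_variant_effects(c(WT = 0, V1 = -1, V2 = 0, V3 = 1),
                              noise_sigma = 1, n_frames = 40L, rng_seed = 3L)
  cond <- list(wt = pl$wt, variants = pl$variants)
  s1 <- rank_stability(cond, n_subsamples = 6L, subsample_frames = 10L,
                       rng_seed = 7L)
  s2 <- rank_stability(cond, n_subsamples = 6L, subsample_frames = 10L,
                       rng_seed = 7L)
  expect_identical(s1$delta_e_norm, s2$delta_e_norm)
  s3 <- rank_stability(cond, n_subsamples = 6L, subsample_frames = 10L,
                       rng_seed = 8L)
  expect_false(identical(s1$delta_e_norm, s3$delta_e_norm))
})

test_that("corrupt frames are excluded and recorded, never dropped silently", {
  toy <- toy20
  broken <- toy
  broken$xyz[2L, ] <- broken$xyz[1L, ] + c(0.01, 0, 0) # overlapping pair
  ens <- new_ensemble(list(toy, broken, toy))
  tmpl <- make_substrate_templates(toy)
  tb <- delta_e_ensemble(ens, tmpl, variant = "WT", max_iter = 5L)
  expect_equal(tb$frame, c(1L, 3L))
  ex <- attr(tb, "excluded")
  expect_equal(ex$frame, 2L)
  expect_match(ex$reason, "overlap")
})

test_that("wild type evaluated against itself yields identical tables", {
  ens <- build_design_ensemble(toy20, n_conformers = 2L, rng_seed = 5L)
  tmpl <- make_substrate_templates(toy20)
  t1 <- delta_e_ensemble(ens, tmpl, variant = "WT", max_iter = 40L)
  t2 <- delta_e_ensemble(ens, tmpl, variant = "WT", max_iter = 40L)
  expect_equal(t1$delta_e, t2$delta_e, tolerance = 1e-12)
  expect_equal(as.numeric(normalize_median(t1, t2)), 1)
})
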