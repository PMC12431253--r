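test_that("mutation composition: A->G removes the side chain, G->A adds CB", {
  g <- apply_mutation(toy20, mutation_spec(5L, "A", "G"))
  expect_equal(nrow(g$atoms), nrow(toy20$atoms) - 1L) # ALA CB removed
  expect_equal(sort(g$atoms$name[g$atoms$res_id == 5L & !g$atoms$het]),
               sort(c("N", "CA", "C", "O")))
  expect_equal(unique(g$atoms$res_name[g$atoms$res_id == 5L & !g$atoms$het]),
               "GLY")

  back <- apply_mutation(g, mutation_spec(5L, "G", "A"))
  expect_equal(nrow(back$atoms), nrow(toy20$atoms))
  added <- back$atoms$name[back$atoms$res_id == 5L & !back$atoms$het]
  expect_setequal(added, c("N", "CA", "C", "O", "CB"))
  # CB at ideal covalent geometry from CA
  ca <- back$xyz[back$atoms$res_id == 5L & back$atoms$name == "CA", ]
  cb <- back$xyz[back$atoms$res_id == 5L & back$atoms$name == "CB", ]
  expect_equal(sqrt(sum((ca - cb)^2)), 1.53, tolerance = 1e-6)
})

test_that("His->Gly renames the residue and leaves the backbone bitwise intact", {
  his <- attr(toy20, "meta")$his
  spec <- parse_variant(paste0("H", his, "G"))[[1L]]
  m <- apply_mutation(toy20, spec)
  expect_equal(unique(m$atoms$res_name[m$atoms$res_id == his & !m$atoms$het]),
               "GLY")
  for (nm in c("N", "CA", "C", "O")) {
    i0 <- which(toy20$atoms$res_id == his & toy20$atoms$name == nm &
                  !toy20$atoms$het)
    i1 <- which(m$atoms$res_id == his & m$atoms$name == nm & !m$atoms$het)
    expect_identical(toy20$xyz[i0, ], m$xyz[i1, ])
  }
  # every atom outside the mutated residue is bitwise unchanged
  out0 <- toy20$xyz[toy20$atoms$res_id != his | toy20$atoms$het, ]
  out1 <- m$xyz[m$atoms$res_id != his | m$atoms$het, ]
  expect_identical(out0, out1)
})

test_that("mismatched or degenerate specs are rejected", {
  expect_error(apply_mutation(toy20, mutation_spec(5L, "W", "G")), "spec error")
  expect_error(mutation_spec(5L, "A", "A"), "must differ")
  expect_error(apply_mutation(toy20, mutation_spec(999L, "A", "G")),
               "spec error")
})

test_that("variant naming round-trips and sorts canonically", {
  sp <- mutation_spec(14L, "H", "G")
  expect_equal(variant_name(sp), "H14G")
  rt <- parse_variant("H14G")[[1L]]
  expect_equal(rt[c("chain", "res_id", "from", "to")],
               sp[c("chain", "res_id", "from", "to")])

  dbl <- list(mutation_spec(56L, "R", "N"), mutation_spec(14L, "H", "G"))
  expect_equal(variant_name(dbl), "H14G_R56N") # sorted by position
  back <- parse_variant("H14G_R56N")
  expect_equal(vapply(back, function(s) s$res_id, integer(1L)), c(14L, 56L))

  set.seed(33)
  for (k in 1:20) {
    from <- sample(ensdesign:::AA1, 1L)
    to <- sample(setdiff(ensdesign:::AA1, from), 1L)
    s <- mutation_spec(sample(300L, 1L), from, to)
    r <- parse_variant(variant_name(s))[[1L]]
    expect_equal(r[c("res_id", "from", "to")], s[c("res_id", "from", "to")])
  }
})

test_that("single enumeration yields 19 minus exclusions per position", {
  one <- enumerate_singles(toy20, positions = 5L)
  expect_length(one, 19L)
  expect_false(any(vapply(one, function(s) s$to == s$from, logical(1L))))
  # stable ordering: alphabetical targets
  expect_equal(vapply(one, function(s) s$to, character(1L)),
               sort(setdiff(ensdesign:::AA1, "A")))

  three <- enumerate_singles(toy20, positions = c(5L, 6L, 8L),
                             excluded = c("C", "P"))
  expect_length(three, 51L) # 3 x 17
  expect_length(enumerate_singles(toy20, positions = integer(0)), 0L)
})

test_that("double enumeration crosses templates with candidate singles", {
  templates <- list(mutation_spec(5L, "A", "G"), mutation_spec(6L, "A", "V"))
  dbl <- enumerate_doubles(templates, toy20, positions = c(8L, 9L))
  expect_length(dbl, 2L * 2L * 19L)
  nms <- vapply(dbl, variant_name, character(1L))
  expect_false(any(duplicated(nms)))
  expect_true(all(grepl("^[A-Z][0-9]+[A-Z]_[A-Z][0-9]+[A-Z]$", nms)))
  # canonical ordering inside each name (positions ascending)
  expect_true("A5G_A8C" %in% nms)
  expect_error(enumerate_doubles(templates, toy20, positions = c(5L, 9L)),
               "overlap")
})

test_that("ensemble-wise mutation keeps members topology-identical", {
  flex <- make_flex_ensemble(toy20, per_res_sigma = 0.3, n_frames = 3L,
                             rng_seed = 6L)$ensemble
  mut <- apply_variant(flex, "A5W")
  expect_s3_class(mut, "Ensemble") # constructor enforces topology identity
  expect_length(mut$members, 3L)
  expect_true(all(vapply(mut$members, function(m)
    "CZ2" %in% m$atoms$name[m$atoms$res_id == 5L], logical(1L))))
})

test_that("a forced clash is flagged, never silent", {
  # mutate a buried-ish position to bulky Trp with an impossible threshold
  expect_warning(
    m <- apply_mutation(toy20, mutation_spec(8L, "A", "W"),
                        clash_cfg = list(factor = 1.6)),
    "clash")
  expect_true(isTRUE(attr(m, "clash_warning")))
})
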