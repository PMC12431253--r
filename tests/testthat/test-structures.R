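test_that("PDB parsing reproduces printed fields", {
  txt <- c(pdb_line(1, "N", "ALA", "A", 1, 1.234, -2.5, 0.001),
           pdb_line(2, "CA", "ALA", "A", 1, 3.000, 4.125, -9.999))
  ens <- read_structure(txt)
  expect_length(ens$members, 1L)
  s <- ens$members[[1L]]
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$xyz[1L, ], c(x = 1.234, y = -2.5, z = 0.001))
  expect_equal(s$xyz[2L, ], c(x = 3.000, y = 4.125, z = -9.999))
  expect_equal(s$atoms$name, c("N", "CA"))
  expect_equal(s$atoms$res_id, c(1L, 1L))
})

test_that("single-model parse agrees with an independent reader", {
  txt <- write_structure(toy20)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, tf)
  ours <- read_structure(txt)$members[[1L]]
  ref <- bio3d::read.pdb(tf)
  expect_equal(unname(matrix(ref$xyz, ncol = 3L, byrow = TRUE)),
               unname(ours$xyz), tolerance = 1e-9)
  expect_equal(ref$atom$elety, ours$atoms$name)
  expect_equal(ref$atom$resno, ours$atoms$res_id)
})

test_that("MODEL blocks become ensemble members; topology is enforced", {
  block <- c(pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0),
             pdb_line(2, "CA", "GLY", "A", 1, 1.46, 0, 0))
  txt3 <- c("MODEL     1", block, "ENDMDL",
            "MODEL     2", block, "ENDMDL",
            "MODEL     3", block, "ENDMDL", "END")
  expect_length(read_structure(txt3)$members, 3L)

  bad <- c("MODEL     1", block, "ENDMDL",
           "MODEL     2", block[1L], "ENDMDL", "END")
  expect_error(read_structure(bad), "topology")
})

test_that("duplicate atoms are rejected; altlocs resolved by occupancy", {
  dup <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
           pdb_line(2, "CA", "ALA", "A", 1, 1, 1, 1))
  expect_error(read_structure(dup), "duplicate")

  alt <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
           pdb_line(2, "CA", "ALA", "A", 1, 5, 5, 5, occ = 0.6, alt = "B"),
           pdb_line(3, "N", "ALA", "A", 1, 9, 9, 9))
  s <- read_structure(alt)$members[[1L]]
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(unname(s$xyz[s$atoms$name == "CA", ]), c(5, 5, 5))

  tie <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.5, alt = "B"),
           pdb_line(2, "CA", "ALA", "A", 1, 5, 5, 5, occ = 0.5, alt = "A"))
  s2 <- read_structure(tie)$members[[1L]]
  expect_equal(unname(s2$xyz[1L, ]), c(5, 5, 5)) # altloc A wins the tie
})

test_that("write/read round-trip is coordinate-identical at 0.001 A", {
  flex <- make_flex_ensemble(toy20, per_res_sigma = 0.3, n_frames = 4L,
                             rng_seed = 2L)$ensemble
  rt <- read_structure(write_structure(flex))
  expect_length(rt$members, 4L)
  for (k in 1:4) {
    expect_lt(max(abs(rt$members[[k]]$xyz - flex$members[[k]]$xyz)), 5.001e-4)
    expect_equal(rt$members[[k]]$atoms$name, flex$members[[k]]$atoms$name)
    expect_equal(rt$members[[k]]$atoms$res_id, flex$members[[k]]$atoms$res_id)
  }
  txt <- write_structure(flex)
  expect_equal(sum(startsWith(txt, "MODEL")), 4L)
  expect_error(write_structure(new_ensemble(list())), "at least one")
})

test_that("selections are index-identical across topology-identical frames", {
  flex <- make_flex_ensemble(toy20, per_res_sigma = 0.5, n_frames = 3L,
                             rng_seed = 3L)$ensemble
  sel <- selection_backbone(res_ids = c(7L, 14L, 19L))
  idx <- lapply(flex$members, select_atoms, sel = sel)
  expect_identical(idx[[1L]], idx[[2L]])
  expect_identical(idx[[1L]], idx[[3L]])
  expect_equal(length(idx[[1L]]), 12L) # 3 residues x N/CA/C/O
  expect_setequal(unique(toy20$atoms$res_id[select_atoms(toy20, sel)]),
                  c(7L, 14L, 19L))
  # default active-site selection carries the canonical residue list
  expect_equal(selection_backbone()$res_id, c(16L, 82L, 83L, 229L, 251L))
})
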