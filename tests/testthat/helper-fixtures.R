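# Shared fixtures, all built in code.

# minimal PDB line in strict fixed-width format
pdb_line <- function(serial, name, res_name, chain, res_id, x, y, z,
                     occ = 1, alt = " ", record = "ATOM", element = NULL) {
  if (is.null(element)) element <- substring(gsub("[0-9]", "", name), 1L, 1L)
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, res_name, chain, res_id, x, y, z, occ, 0,
          element)
}

# bare structure from a coordinate matrix (one CA per residue)
ca_structure <- function(xyz, label = "toy") {
  n <- nrow(xyz)
  new_structure(data.frame(serial = seq_len(n), name = "CA", element = "C",
                           res_name = "ALA", res_id = seq_len(n), chain = "A",
                           stringsAsFactors = FALSE),
                xyz, label = label)
}

# 3-atom donor/hydrogen/acceptor frame with chosen D-A distance and D-H-A angle
dha_frame <- function(dist, angle) {
  D <- c(0, 0, 0)
  H <- c(1.01, 0, 0)
  th <- angle * pi / 180
  # |HA| solving the triangle for the requested |DA| (positive root)
  b <- 2 * 1.01 * cos(th)
  w <- (b + sqrt(b^2 - 4 * (1.01^2 - dist^2))) / 2
  A <- H + w * c(-cos(th), sin(th), 0)
  new_structure(data.frame(serial = 1:3, name = c("N", "H", "O"),
                           element = c("N", "H", "O"),
                           res_name = c("GLY", "GLY", "HOH"), res_id = 1L,
                           chain = c("A", "A", "X"),
                           het = c(FALSE, FALSE, TRUE),
                           stringsAsFactors = FALSE),
                rbind(D, H, A))
}

dha_defn <- hbond_definition(1L, donor = atom_spec(1L, "N", "A"),
                             acceptor = atom_spec(1L, "O", "X"),
                             hydrogen = atom_spec(1L, "H", "A"))

# toy enzyme shared across tests (deterministic)
toy20 <- make_toy_enzyme(20L, rng_seed = 1L)

# independent re-measurement of every bound (the brute-force oracle used by
# the bound-satisfaction checks; deliberately not check_bounds())
oracle_max_violation <- function(x, boundset) {
  b <- boundset$bounds
  worst <- 0
  for (k in seq_len(nrow(b))) {
    d <- sqrt(sum((x$xyz[b$i[k], ] - x$xyz[b$j[k], ])^2))
    v <- max(b$lower[k] - d, d - b$upper[k], 0)
    if (v > worst) worst <- v
  }
  worst
}

# two-atom structure at a given separation (HETATM, chargeless by default)
pair_structure <- function(r, names = c("Q1", "Q2"), element = "C") {
  new_structure(data.frame(serial = 1:2, name = names, element = element,
                           res_name = "LIG", res_id = 1:2, chain = "X",
                           het = TRUE, stringsAsFactors = FALSE),
                rbind(c(0, 0, 0), c(r, 0, 0)))
}
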