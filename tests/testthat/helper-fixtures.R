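# shared fixtures built in code (no binary data shipped)

# short time grid for cheap kernel tests
short_time_grid <- function() seq(0, 1600, by = 16)

# a noiseless trace with known lambda and background
make_clean_trace <- function(means = 3.7, sigmas = 0.15, areas = 1,
                             lambda = 0.19, rate = 1e-4,
                             t_grid = default_time_grid(),
                             r_grid = default_distance_grid()) {
  comp <- Map(function(m, s, a) c(m, s, a), means, sigmas, areas)
  P <- gaussian_mixture(comp, r_grid)
  K <- kernel_matrix(t_grid, r_grid)
  FF <- form_factor(P, lambda, K)
  apply_background(FF, background_model(rate, 3))
}

# minimal hand-written PDB text: a uridine-like pyrimidine residue with
# ring + C1' atoms in the z = 0 plane, centered near the origin
pdb_pyrimidine_lines <- function(chain = "A", resi = 1, shift = c(0, 0, 0),
                                 resn = "U") {
  ring <- rbind(
    `C1'` = c(-2.40, -1.20, 0),
    N1 = c(-1.20, -0.70, 0),
    C2 = c(-1.20, 0.70, 0),
    N3 = c(0.00, 1.40, 0),
    C4 = c(1.20, 0.70, 0),
    C5 = c(1.20, -0.70, 0),
    C6 = c(0.00, -1.40, 0))
  ring <- sweep(ring, 2, shift, `+`)
  vapply(seq_len(nrow(ring)), function(i) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            i, rownames(ring)[i], resn, chain, resi,
            ring[i, 1], ring[i, 2], ring[i, 3],
            substr(rownames(ring)[i], 1, 1))
  }, character(1))
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a bare rotamer_ensemble holding fixed NO positions (for pair-distance
# tests that do not need a structure)
point_ensemble <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3)
  structure(list(site = list(chain = "X", resi = 0L),
                 n_requested = nrow(xyz), n_accepted = nrow(xyz),
                 no_coords = xyz,
                 weights = rep(1 / nrow(xyz), nrow(xyz))),
            class = "rotamer_ensemble")
}
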