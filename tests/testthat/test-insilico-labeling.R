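test_that("PDB reader: fixture round trip, altloc and model handling", {
  path <- write_pdb_fixture(c(pdb_pyrimidine_lines("A", 1),
                              pdb_pyrimidine_lines("A", 2, shift = c(0, 0, 3.4))))
  s <- read_structure(path)
  expect_s3_class(s, "rna_structure")
  expect_equal(nrow(s), 14)
  expect_equal(sort(unique(s$resi)), c(1, 2))
  expect_equal(sum(s$atom == "C5"), 2)

  # altloc: keep only the highest-occupancy copy
  alt <- c(
    "ATOM      1  C5 AU   A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  C5 BU   A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  C6  U   A   1       0.000   1.400   0.000  1.00  0.00           C")
  s2 <- read_structure(write_pdb_fixture(alt))
  expect_equal(nrow(s2), 2)
  expect_equal(s2$x[s2$atom == "C5"], 1.0)

  # multi-model: model 1 only, with a warning
  mm <- c("MODEL     1", pdb_pyrimidine_lines("A", 1), "ENDMDL",
          "MODEL     2", pdb_pyrimidine_lines("A", 1, shift = c(9, 9, 9)),
          "ENDMDL")
  expect_warning(s3 <- read_structure(write_pdb_fixture(mm)), "model 1")
  expect_equal(nrow(s3), 7)
  expect_error(read_structure(tempfile()), "not found")
})

test_that("label sites require pyrimidine frame atoms", {
  path <- write_pdb_fixture(pdb_pyrimidine_lines("A", 1))
  s <- read_structure(path)
  site <- label_site(s, "A", 1)
  expect_equal(site$origin, unname(unlist(
    s[s$atom == "C5", c("x", "y", "z")])))
  # exocyclic direction is in-plane, unit length, away from ring center
  expect_equal(sqrt(sum(site$exo^2)), 1)
  expect_equal(sum(site$exo * site$normal), 0, tolerance = 1e-12)
  expect_error(label_site(s, "B", 1), "not found")

  g_lines <- c(
    "ATOM      1  C1' G   A   1      -2.400  -1.200   0.000  1.00  0.00           C",
    "ATOM      2  N9  G   A   1      -1.200  -0.700   0.000  1.00  0.00           N",
    "ATOM      3  C8  G   A   1      -1.100   0.700   0.000  1.00  0.00           C")
  sg <- read_structure(write_pdb_fixture(g_lines))
  expect_error(label_site(sg, "A", 1), "purine")
})

test_that("rotamer sampling: free site, wall exclusion, determinism", {
  free <- read_structure(write_pdb_fixture(pdb_pyrimidine_lines("A", 1)))
  e <- build_label_rotamers(free, list(chain = "A", resi = 1),
                            n = 400, seed = 1)
  expect_equal(e$n_accepted, 400)   # nothing to clash with

  # NO positions all within the maximal label extension of the origin
  site <- label_site(free, "A", 1)
  reach <- sqrt(rowSums(sweep(e$no_coords, 2, site$origin)^2))
  expect_lt(max(reach), 14)

  # wall of dummy atoms 3 A to one side: accepted NO positions stay in
  # the open half-space
  wall <- expand.grid(x = seq(-12, 12, by = 1.2), y = seq(-12, 12, by = 1.2))
  wall_lines <- vapply(seq_len(nrow(wall)), function(i) {
    sprintf("ATOM  %5d  C   WAL B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, 900 + i, wall$x[i], wall$y[i], 3.0)
  }, character(1))
  sw <- read_structure(write_pdb_fixture(c(pdb_pyrimidine_lines("A", 1),
                                           wall_lines)))
  ew <- build_label_rotamers(sw, list(chain = "A", resi = 1),
                             n = 600, seed = 2)
  expect_gt(ew$n_accepted, 0)
  expect_true(all(ew$no_coords[, 3] < 3.0))

  # same seed reproduces; different seeds agree in the mean
  e2 <- build_label_rotamers(free, list(chain = "A", resi = 1),
                             n = 400, seed = 1)
  expect_identical(e$no_coords, e2$no_coords)
  big1 <- build_label_rotamers(free, list(chain = "A", resi = 1),
                               n = 2000, seed = 10)
  big2 <- build_label_rotamers(free, list(chain = "A", resi = 1),
                               n = 2000, seed = 20)
  shift <- sqrt(sum((colMeans(big1$no_coords) - colMeans(big2$no_coords))^2))
  expect_lt(shift / 10, 0.1)   # nm

  expect_error(build_label_rotamers(free, list(chain = "A", resi = 1),
                                    n = 50), ">= 100")
})

test_that("tightening the clash cutoff never gains conformers", {
  s <- build_a_form_duplex("GGCAUGCAUGCC")
  counts <- vapply(c(1.5, 2.0, 2.5, 3.0), function(cut) {
    build_label_rotamers(s, list(chain = "A", resi = 5), n = 300,
                         seed = 4, clash_cutoff = cut)$n_accepted
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pair distributions: point ensembles, symmetry, rigid motion", {
  e1 <- point_ensemble(c(0, 0, 0))
  e2 <- point_ensemble(c(40, 0, 0))
  P <- label_pair_distribution(e1, e2)
  expect_equal(attr(P, "mean_nm"), 4.0)
  expect_equal(P$r_grid[which.max(P$density)], 4.0,
               tolerance = diff(P$r_grid[1:2]))
  P21 <- label_pair_distribution(e2, e1)
  expect_equal(P$density, P21$density)

  # rigid-body transform of the whole structure leaves the mean invariant
  s <- build_a_form_duplex("GGCAUGCAUGCC")
  ea <- build_label_rotamers(s, list(chain = "A", resi = 5), n = 300, seed = 1)
  eb <- build_label_rotamers(s, list(chain = "B", resi = 5), n = 300, seed = 2)
  m0 <- attr(label_pair_distribution(ea, eb), "mean_nm")
  th <- 0.8; ax <- c(cos(th), sin(th), 0)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s2 <- s
  xyz <- t(R %*% t(as.matrix(s[, c("x", "y", "z")]))) +
    matrix(c(11, -3, 7), nrow(s), 3, byrow = TRUE)
  s2$x <- xyz[, 1]; s2$y <- xyz[, 2]; s2$z <- xyz[, 3]
  ea2 <- build_label_rotamers(s2, list(chain = "A", resi = 5), n = 300, seed = 1)
  eb2 <- build_label_rotamers(s2, list(chain = "B", resi = 5), n = 300, seed = 2)
  m1 <- attr(label_pair_distribution(ea2, eb2), "mean_nm")
  expect_equal(m0, m1, tolerance = 1e-9)

  # histogram integrates to 1
  dr <- diff(P$r_grid[1:2])
  d <- P$density
  expect_equal(sum((d[-1] + d[-length(d)]) / 2 * dr), 1, tolerance = 1e-9)
})

test_that("A-form duplex builder: helical arithmetic and validation", {
  s <- build_a_form_duplex("GCGCAUGCGC")
  z1 <- s[s$chain == "A" & s$resi == 1 & s$atom == "C1'", "z"]
  z10 <- s[s$chain == "A" & s$resi == 10 & s$atom == "C1'", "z"]
  expect_equal(z10 - z1, 9 * 2.81, tolerance = 1e-9)
  expect_equal(360 / 32.7, 11.0, tolerance = 0.01)  # one turn ~ 11 bp

  # residue azimuths advance by the twist
  c1 <- s[s$chain == "A" & s$atom == "C1'", ]
  phi <- atan2(c1$y, c1$x)
  dphi <- diff(phi) %% (2 * pi)
  expect_equal(dphi, rep(32.7 * pi / 180, 9), tolerance = 1e-9)

  # complementarity is validated naming the first mismatch
  expect_error(build_a_form_duplex("GCAA", "UUCC"), "position 2")
  expect_error(build_a_form_duplex("GGUU", "AACA"), "position 1")
  expect_error(build_a_form_duplex("GGA", "UCCC"), "equal length")
  expect_silent(build_a_form_duplex("GUAC"))
  expect_equal(reverse_complement("GGAC"), "GUCC")
})

test_that("placeholder duplexes carry uridines at the labeling positions", {
  for (cs in list(c("P1_U18", 18), c("P1_U20", 20), c("P2_U14", 14))) {
    sq <- placeholder_sequence(cs[1])
    pos <- as.integer(cs[2])
    expect_equal(nchar(sq), 23)
    expect_equal(substr(sq, pos, pos), "U")
    rc <- reverse_complement(sq)
    expect_equal(substr(rc, pos, pos), "U")
    # both strands accept a label at that position
    s <- build_a_form_duplex(sq)
    expect_s3_class(label_site(s, "A", pos), "label_site")
    expect_s3_class(label_site(s, "B", pos), "label_site")
  }
})
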