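#' Read an RNA structure from a PDB file
#'
#' Minimal fixed-column PDB reader: ATOM/HETATM records of the first
#' model, heavy atoms only (hydrogens and element D ignored), alternate
#' locations resolved to the highest-occupancy copy. No pre-installed R
#' package in this stack parses PDB, hence the dedicated reader.
#'
#' @param path PDB file path.
#' @return object of class `rna_structure`: a data.frame with columns
#'   `chain`, `resi`, `resn`, `atom`, `element`, `x`, `y`, `z`
#'   (coordinates in Angstrom).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) {
    if (length(grep("^MODEL", lines)) > 1) {
      warning("multi-model file: using model 1 only")
    }
    lines <- lines[seq_len(endmdl[1] - 1)]
  }
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  fx <- function(a, b) trimws(substr(rec, a, b))
  atom <- fx(13, 16)
  altloc <- fx(17, 17)
  resn <- fx(18, 20)
  chain <- fx(22, 22)
  resi <- as.integer(fx(23, 26))
  x <- as.numeric(fx(31, 38))
  y <- as.numeric(fx(39, 46))
  z <- as.numeric(fx(47, 54))
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[is.na(occ)] <- 1
  element <- fx(77, 78)
  guess <- substr(gsub("^[0-9']+", "", atom), 1, 1)
  element <- ifelse(nzchar(element), element, guess)
  df <- data.frame(chain = chain, resi = resi, resn = resn, atom = atom,
                   element = element, x = x, y = y, z = z, occ = occ,
                   altloc = altloc, stringsAsFactors = FALSE)
  df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]
  if (any(!is.finite(df$x + df$y + df$z))) stop("non-finite coordinates in ", path)
  # altloc: keep highest occupancy per (chain, resi, atom)
  key <- paste(df$chain, df$resi, df$atom, sep = "|")
  df <- df[order(key, -df$occ), , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resi, df$atom, sep = "|")), ,
           drop = FALSE]
  df$occ <- NULL
  df$altloc <- NULL
  rownames(df) <- NULL
  if (nrow(df) == 0) stop("no heavy atoms in ", path)
  structure(df, class = c("rna_structure", "data.frame"))
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(paste(x$chain, x$resi))),
              paste(sort(unique(x$chain)), collapse = ", ")))
  invisible(x)
}

#' Spin-labeling site on a pyrimidine base
#'
#' Identifies the attachment residue and precomputes the attachment
#' frame: origin at the base C5 atom, in-plane exocyclic direction (away
#' from the ring centroid, where the C5 substituent points) and the ring
#' normal. Any pyrimidine is accepted in place of uridine (frame reuse);
#' purines are refused.
#'
#' @param structure an `rna_structure`.
#' @param chain chain identifier.
#' @param resi residue index (source-file numbering).
#' @return object of class `label_site` with `chain`, `resi`, `origin`,
#'   `exo` (unit vector), `normal` (unit vector).
#' @export
label_site <- function(structure, chain, resi) {
  stopifnot(inherits(structure, "rna_structure"))
  res <- structure[structure$chain == chain & structure$resi == resi, ,
                   drop = FALSE]
  if (nrow(res) == 0) stop(sprintf("residue %s:%s not found", chain, resi))
  if ("N9" %in% res$atom) {
    stop(sprintf("residue %s:%s is a purine; labeling requires a pyrimidine",
                 chain, resi))
  }
  need <- c("C5", "C6")
  if (!all(need %in% res$atom)) {
    stop(sprintf("residue %s:%s lacks the C5/C6 frame atoms", chain, resi))
  }
  get <- function(a) unlist(res[res$atom == a, c("x", "y", "z")], use.names = FALSE)
  c5 <- get("C5")
  c6 <- get("C6")
  third <- if ("C4" %in% res$atom) get("C4") else if ("N1" %in% res$atom) {
    get("N1")
  } else stop(sprintf("residue %s:%s lacks a third ring atom (C4 or N1)",
                      chain, resi))
  ring_atoms <- intersect(c("N1", "C2", "N3", "C4", "C5", "C6"), res$atom)
  centroid <- colMeans(res[res$atom %in% ring_atoms, c("x", "y", "z")])
  normal <- vnorm(vcross(c6 - c5, third - c5))
  exo <- c5 - centroid
  exo <- vnorm(exo - sum(exo * normal) * normal)   # project into ring plane
  base::structure(list(chain = chain, resi = resi, origin = c5, exo = exo,
                       normal = normal, c6 = c6),
                  class = "label_site")
}

vnorm <- function(v) v / sqrt(sum(v^2))
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place an atom from internal coordinates (NeRF): distance to C,
# angle B-C-X (deg), dihedral A-B-C-X (deg)
place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- vnorm(C - B)
  n <- vnorm(vcross(B - A, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(dih),
         bond * sin(ang) * sin(dih))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Idealized internal coordinates of the triazole-linked tetraethyl-
# isoindoline nitroxide, coarse-grained to one pseudo-atom per rigid
# fragment. Bond lengths/angles fixed; chi1-chi3 are the free dihedrals.
# Rows: name, parent triplet (indices into the growing atom list, with
# 1 = base C6, 2 = base C5, 3 = first label atom, ...), bond (A),
# angle (deg), dihedral (deg or NA for a sampled chi).
label_topology <- function() {
  list(
    # triazole C4 attached to base C5, in the base plane, trans to C6
    list(name = "CT4", ref = c("N_prev", "C6", "C5"), bond = 1.43,
         angle = 120, dihedral = 180, chi = NA),
    # triazole N1 across the ring (1,4-disubstitution)
    list(name = "NT1", ref = c("C6", "C5", "CT4"), bond = 2.20,
         angle = 150, dihedral = NA, chi = 1),
    # ring-centroid pseudo-atom for clash checks
    list(name = "RC", ref = c("C6", "C5", "CT4"), bond = 1.15,
         angle = 155, dihedral = NA, chi = 1),
    # methylene linker carbon
    list(name = "CM", ref = c("C5", "CT4", "NT1"), bond = 1.46,
         angle = 126, dihedral = NA, chi = 2),
    # isoindoline attachment carbon
    list(name = "CA", ref = c("CT4", "NT1", "CM"), bond = 1.51,
         angle = 112, dihedral = NA, chi = 3),
    # mid-ring pseudo-atom of the isoindoline bicycle
    list(name = "RB", ref = c("NT1", "CM", "CA"), bond = 1.85,
         angle = 150, dihedral = 180, chi = NA),
    # NO nitrogen at the far end of the rigid isoindoline
    list(name = "NN", ref = c("NT1", "CM", "CA"), bond = 3.70,
         angle = 150, dihedral = 180, chi = NA),
    # NO oxygen
    list(name = "ON", ref = c("CM", "CA", "NN"), bond = 1.28,
         angle = 160, dihedral = 180, chi = NA)
  )
}

# build label atom coordinates for one set of dihedrals chi (degrees).
# Returns a matrix with rownames = atom names.
build_label_conformer <- function(site, chi) {
  # anchor triad: a pseudo "previous" atom to define the first dihedral;
  # use the point opposite the exocyclic direction rotated out of plane
  coords <- list(
    N_prev = site$origin - site$exo - site$normal,  # any non-collinear ref
    C6 = site$c6,
    C5 = site$origin
  )
  # first atom placed analytically in-plane along the exocyclic direction
  coords$CT4 <- site$origin + 1.43 * site$exo
  topo <- label_topology()
  for (item in topo[-1]) {
    dih <- if (is.na(item$dihedral)) chi[item$chi] else item$dihedral
    # chi rotations 2 and 3 are offsets on top of the sampled values for
    # atoms sharing a rotation axis (RC shares chi1 with NT1)
    A <- coords[[item$ref[1]]]
    B <- coords[[item$ref[2]]]
    C <- coords[[item$ref[3]]]
    coords[[item$name]] <- place_atom(A, B, C, item$bond, item$angle, dih)
  }
  keep <- c("CT4", "NT1", "RC", "CM", "CA", "RB", "NN", "ON")
  out <- do.call(rbind, coords[keep])
  rownames(out) <- keep
  out
}

#' Accessible-volume rotamer ensemble of the nitroxide label
#'
#' Attaches the triazole-linked isoindoline nitroxide to a pyrimidine C5
#' using idealized internal coordinates, samples its three free dihedrals
#' uniformly at random, and accepts a conformer only if none of its heavy
#' (pseudo-)atoms lies within `clash_cutoff` of any structure heavy atom
#' outside the attachment residue. This is an accessible-volume model: no
#' torsion-energy weighting, uniform weights over accepted conformers.
#'
#' @param structure an `rna_structure`.
#' @param site a [label_site()] (or list with `chain`, `resi`).
#' @param n number of requested conformers, >= 100.
#' @param seed integer seed (deterministic ensembles).
#' @param clash_cutoff heavy-atom clash distance in Angstrom, default 2.5.
#' @return object of class `rotamer_ensemble`: `site`, `n_requested`,
#'   `n_accepted`, `no_coords` (matrix of accepted NO-nitrogen positions,
#'   Angstrom), `weights` (uniform).
#' @export
build_label_rotamers <- function(structure, site, n = 1000, seed = 1L,
                                 clash_cutoff = 2.5) {
  stopifnot(inherits(structure, "rna_structure"))
  if (!inherits(site, "label_site")) {
    site <- label_site(structure, site$chain, site$resi)
  }
  if (n < 100) stop("`n` must be >= 100 for a stable ensemble")
  env <- structure[!(structure$chain == site$chain &
                       structure$resi == site$resi), , drop = FALSE]
  env_xyz <- as.matrix(env[, c("x", "y", "z")])
  # prune environment to a sphere that can possibly clash (max reach
  # ~10.5 A from C5 plus cutoff)
  if (nrow(env_xyz) > 0) {
    d2 <- rowSums(sweep(env_xyz, 2, site$origin)^2)
    env_xyz <- env_xyz[d2 <= (14 + clash_cutoff)^2, , drop = FALSE]
  }
  chis <- withr_seed(seed, matrix(stats::runif(3 * n, 0, 360), ncol = 3))
  cut2 <- clash_cutoff^2
  acc <- matrix(NA_real_, nrow = n, ncol = 3)
  n_acc <- 0L
  for (i in seq_len(n)) {
    conf <- build_label_conformer(site, chis[i, ])
    ok <- TRUE
    if (nrow(env_xyz) > 0) {
      for (j in seq_len(nrow(conf))) {
        dd <- (env_xyz[, 1] - conf[j, 1])^2 + (env_xyz[, 2] - conf[j, 2])^2 +
          (env_xyz[, 3] - conf[j, 3])^2
        if (any(dd < cut2)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      n_acc <- n_acc + 1L
      acc[n_acc, ] <- conf["NN", ]
    }
  }
  if (n_acc < 0.01 * n) {
    stop(sprintf(
      "buried site %s:%s: only %d of %d conformers clash-free (cutoff %.2f A)",
      site$chain, site$resi, n_acc, n, clash_cutoff))
  }
  base::structure(list(site = site, n_requested = n, n_accepted = n_acc,
                       no_coords = acc[seq_len(n_acc), , drop = FALSE],
                       weights = rep(1 / n_acc, n_acc)),
                  class = "rotamer_ensemble")
}

#' @export
print.rotamer_ensemble <- function(x, ...) {
  cat(sprintf("<rotamer_ensemble> site %s:%s, %d/%d accepted\n",
              x$site$chain, x$site$resi, x$n_accepted, x$n_requested))
  invisible(x)
}

#' Inter-label N-N distance distribution from two rotamer ensembles
#'
#' Histogram of all pairwise distances between the NO-nitrogen positions
#' of two ensembles, binned onto the analysis distance grid and
#' normalized to unit integral.
#'
#' @param e1,e2 [build_label_rotamers()] ensembles.
#' @param r_grid distance grid in nm.
#' @return a [distance_distribution()] with attributes `mean_nm` and
#'   `sd_nm`.
#' @export
label_pair_distribution <- function(e1, e2,
                                    r_grid = default_distance_grid()) {
  stopifnot(inherits(e1, "rotamer_ensemble"), inherits(e2, "rotamer_ensemble"))
  a <- e1$no_coords
  b <- e2$no_coords
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  d_nm <- sqrt(pmax(d2, 0)) / 10
  dr <- r_grid[2] - r_grid[1]
  breaks <- c(r_grid - dr / 2, max(r_grid) + dr / 2)
  d_clamped <- pmin(pmax(as.vector(d_nm), min(breaks) + 1e-12),
                    max(breaks) - 1e-12)
  counts <- tabulate(findInterval(d_clamped, breaks), nbins = length(r_grid))
  P <- distance_distribution(r_grid, counts)
  attr(P, "mean_nm") <- mean(d_nm)
  attr(P, "sd_nm") <- stats::sd(as.vector(d_nm))
  P
}

#' Generate an idealized A-form RNA duplex
#'
#' Builds a duplex from a strand and its reverse complement using fixed
#' A-form helical parameters: rise 2.81 Angstrom and twist 32.7 degrees
#' per base pair, with the base-pair plane displaced 4.4 Angstrom from
#' the helix axis (the displacement that creates the deep, narrow major
#' groove of A-RNA). Emits C1', the glycosidic nitrogen, and the base
#' ring atoms needed for label attachment (full pyrimidine ring;
#' N9/C8 for purines). Wobble pairs are rejected.
#'
#' @param seq1 RNA sequence of strand A (5'->3', characters ACGU).
#' @param seq2 RNA sequence of strand B; must be the reverse complement
#'   of `seq1`. Defaults to it.
#' @return an `rna_structure` with chains "A" and "B"; residue i of chain
#'   B pairs residue n + 1 - i of chain A.
#' @export
build_a_form_duplex <- function(seq1, seq2 = reverse_complement(seq1)) {
  s1 <- toupper(strsplit(gsub("\\s", "", seq1), "")[[1]])
  s2 <- toupper(strsplit(gsub("\\s", "", seq2), "")[[1]])
  if (length(s1) != length(s2)) stop("strands must have equal length")
  if (!all(s1 %in% c("A", "C", "G", "U")) || !all(s2 %in% c("A", "C", "G", "U"))) {
    stop("sequences must contain only A, C, G, U")
  }
  n <- length(s1)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  for (i in seq_len(n)) {
    partner <- s2[n + 1 - i]
    if (comp[[s1[i]]] != partner) {
      stop(sprintf(
        "non-complementary pair at position %d: %s does not pair %s (Watson-Crick only)",
        i, s1[i], partner))
    }
  }
  rise <- 2.81
  twist <- 32.7 * pi / 180
  x_disp <- -4.4
  rows <- list()
  for (i in seq_len(n)) {
    th <- (i - 1) * twist
    zz <- (i - 1) * rise
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    for (strand in 1:2) {
      base <- if (strand == 1) s1[i] else s2[n + 1 - i]
      tmpl <- nucleotide_template(base, strand)
      resi <- if (strand == 1) i else n + 1 - i
      xyz <- tmpl$xyz
      xyz[, 1] <- xyz[, 1] + x_disp
      xyz <- t(R %*% t(xyz))
      xyz[, 3] <- xyz[, 3] + zz
      rows[[length(rows) + 1]] <- data.frame(
        chain = if (strand == 1) "A" else "B", resi = resi, resn = base,
        atom = tmpl$atoms, element = substr(tmpl$atoms, 1, 1),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$element <- ifelse(grepl("^C1", df$atom), "C", df$element)
  df <- df[order(df$chain, df$resi), , drop = FALSE]
  # coarse backbone: a sugar-center pseudo-atom outside each C1' and a
  # phosphate bridging consecutive residues, both at A-form backbone
  # radii (~9.3 A). They form the major-groove walls that make the
  # accessible-volume clash filter meaningful.
  bb <- list()
  for (ch in unique(df$chain)) {
    c1 <- df[df$chain == ch & df$atom == "C1'", , drop = FALSE]
    c1 <- c1[order(c1$resi), , drop = FALSE]
    to_radius <- function(p, rad) {
      rho <- sqrt(p[1]^2 + p[2]^2)
      c(p[1] * rad / rho, p[2] * rad / rho, p[3])
    }
    for (j in seq_len(nrow(c1))) {
      pj <- unlist(c1[j, c("x", "y", "z")], use.names = FALSE)
      sug <- to_radius(pj, 9.3)
      bb[[length(bb) + 1]] <- data.frame(
        chain = ch, resi = c1$resi[j], resn = c1$resn[j], atom = "C4'",
        element = "C", x = sug[1], y = sug[2], z = sug[3],
        stringsAsFactors = FALSE)
      if (j > 1) {
        pprev <- unlist(c1[j - 1, c("x", "y", "z")], use.names = FALSE)
        ph <- to_radius((pj + pprev) / 2, 9.4)
        bb[[length(bb) + 1]] <- data.frame(
          chain = ch, resi = c1$resi[j], resn = c1$resn[j], atom = "P",
          element = "P", x = ph[1], y = ph[2], z = ph[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- rbind(df, do.call(rbind, bb))
  df <- df[order(df$chain, df$resi), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("rna_structure", "data.frame"))
}

#' Reverse complement of an RNA sequence
#' @param seq RNA sequence string (ACGU).
#' @return character string.
#' @export
reverse_complement <- function(seq) {
  s <- toupper(strsplit(gsub("\\s", "", seq), "")[[1]])
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  if (!all(s %in% names(comp))) stop("sequence must contain only A, C, G, U")
  paste(rev(unname(comp[s])), collapse = "")
}

# Base-pair-frame template coordinates (Angstrom) for one nucleotide.
# Pair frame: x from the helix axis toward the base pair, pairing axis
# along y, pair plane z = 0. Strand 2 is the strand-1 template rotated
# 180 degrees about the pair-frame x axis (y -> -y, z -> -z).
nucleotide_template <- function(base, strand) {
  # glycosidic geometry: C1'-C1' 10.4 A, glycosidic angle 54.5 deg;
  # frame follows the standard base-pair convention: origin at the pair
  # center, +x toward the major groove, C1' on the minor-groove side
  c1 <- c(-2.47, -5.2, 0)
  lam <- 54.5 * pi / 180
  gdir <- c(sin(lam), cos(lam), 0)           # C1' -> glycosidic N
  ng <- c1 + 1.48 * gdir
  is_pyr <- base %in% c("C", "U")
  if (is_pyr) {
    ctr <- ng + 1.38 * gdir                  # ring center along glycosidic bond
    ang0 <- atan2(ng[2] - ctr[2], ng[1] - ctr[1])
    # ring order N1, C2, N3, C4, C5, C6; orientation chosen so that N3
    # faces the pairing partner (+y) and C5/C6 the major groove
    angs <- ang0 + (0:5) * (-60) * pi / 180
    ring <- cbind(ctr[1] + 1.38 * cos(angs), ctr[2] + 1.38 * sin(angs), 0)
    if (ring[3, 2] < ng[2]) {                # wrong handedness: flip
      angs <- ang0 + (0:5) * (60) * pi / 180
      ring <- cbind(ctr[1] + 1.38 * cos(angs), ctr[2] + 1.38 * sin(angs), 0)
    }
    atoms <- c("C1'", "N1", "C2", "N3", "C4", "C5", "C6")
    xyz <- rbind(c1, ring)
  } else {
    # purine: glycosidic N9 and imidazole C8 toward the major groove
    ctr <- ng + 1.2 * gdir
    perp <- c(-gdir[2], gdir[1], 0)
    c8 <- ng + 1.37 * vnorm(0.35 * gdir - perp)
    if (c8[2] > ng[2]) c8 <- ng + 1.37 * vnorm(0.35 * gdir + perp)
    atoms <- c("C1'", "N9", "C8")
    xyz <- rbind(c1, ng, c8)
  }
  if (strand == 2) {
    xyz[, 2] <- -xyz[, 2]
    xyz[, 3] <- -xyz[, 3]
  }
  list(atoms = atoms, xyz = xyz)
}
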