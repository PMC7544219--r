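#' Synthetic-scenario catalogue
#'
#' Ground-truth scenarios emulating PELDOR samples of spin-labeled
#' riboswitch stem loops under three guanidinium conditions (no ligand,
#' 0.4 mM, 40 mM). Components are (mean nm, sigma nm, area) Gaussians, or
#' a flat 3-6 nm density for conformationally heterogeneous samples.
#' Modulation depths are the experimentally observed values; for the two
#' U20 single-hairpin scenarios only dimer percentages (43% / 57%) are
#' observed, and the preset derives lambda = fraction x 0.35 (recorded in
#' the manifest).
#'
#' @param name preset name; see Details.
#' @details Presets: `P2_noGdm` (broad 3-6 nm, lambda 0.08), `P2_Gdm`
#'   (3.7 nm, 0.19), `P1U18_noGdm` (4.8 nm, 0.27), `P1U18_Gdm04`
#'   (4.8/4.1 nm at 0.68/0.32, 0.34), `P1U18_Gdm40` (4.1 nm, 0.32),
#'   `P1U20_noGdm` (5.7 nm, 0.43 x 0.35), `P1U20_Gdm` (5.2 nm,
#'   0.57 x 0.35), `mixU18_Gdm` (4.0 nm, 0.30), `mixU20_noGdm`
#'   (4.2 + 5.6 nm, 0.13), `mixU20_Gdm` (3.6/4.4/5.2 nm at
#'   0.25/0.50/0.25, 0.23).
#' @return object of class `scenario_config`: `name`, `components` (list
#'   of c(mean, sigma, area)) or `broad = TRUE`, `lambda_true`,
#'   `background_rate`, `noise_sigma`, `seed`, `label`, `t_max`, `dt`.
#' @export
preset <- function(name) {
  cat_ <- preset_catalogue()
  if (!name %in% names(cat_)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(cat_), collapse = ", "))
  }
  cat_[[name]]
}

#' @rdname preset
#' @export
preset_names <- function() names(preset_catalogue())

DEFAULT_COMPONENT_SIGMA <- 0.15   # nm, sharp kissing-loop peak
DEFAULT_NOISE_SIGMA <- 0.005      # relative to V(0)
DEFAULT_BACKGROUND_RATE <- 1e-4   # ns^-1, mild 3D background
LAMBDA_FULL_DIMER <- 0.35         # full-dimer reference depth

preset_catalogue <- function() {
  sg <- DEFAULT_COMPONENT_SIGMA
  mk <- function(name, components, lambda, label, broad = FALSE) {
    # dipolar evolution window covering >= 2.5 periods of the slowest
    # stated component (capped at 10 us, which deuterated samples reach),
    # mirroring how an experimentalist sizes the window to the expected
    # distance range; step sized for ~300-400 points
    long <- if (broad) 6 else max(vapply(components, `[`, numeric(1), 1))
    period <- long^3 / 52.04e-3            # ns per dipolar cycle
    t_max <- max(2500, min(10000, 500 * ceiling(2.5 * period / 500)))
    dt <- max(8, 8 * ceiling(t_max / 400 / 8))
    base::structure(list(
      name = name, components = components, broad = broad,
      lambda_true = lambda, background_rate = DEFAULT_BACKGROUND_RATE,
      noise_sigma = DEFAULT_NOISE_SIGMA, seed = 1L, label = label,
      t_max = t_max, dt = dt), class = "scenario_config")
  }
  list(
    P2_noGdm = mk("P2_noGdm", list(), 0.08, "-Gdm", broad = TRUE),
    P2_Gdm = mk("P2_Gdm", list(c(3.7, sg, 1)), 0.19, "+Gdm 0.4 mM"),
    P1U18_noGdm = mk("P1U18_noGdm", list(c(4.8, sg, 1)), 0.27, "-Gdm"),
    P1U18_Gdm04 = mk("P1U18_Gdm04",
                     list(c(4.8, sg, 0.68), c(4.1, sg, 0.32)), 0.34,
                     "+Gdm 0.4 mM"),
    P1U18_Gdm40 = mk("P1U18_Gdm40", list(c(4.1, sg, 1)), 0.32,
                     "++Gdm 40 mM"),
    P1U20_noGdm = mk("P1U20_noGdm", list(c(5.7, sg, 1)),
                     0.43 * LAMBDA_FULL_DIMER, "-Gdm"),
    P1U20_Gdm = mk("P1U20_Gdm", list(c(5.2, sg, 1)),
                   0.57 * LAMBDA_FULL_DIMER, "++Gdm 40 mM"),
    mixU18_Gdm = mk("mixU18_Gdm", list(c(4.0, sg, 1)), 0.30,
                    "++Gdm 40 mM"),
    mixU20_noGdm = mk("mixU20_noGdm",
                      list(c(4.2, sg, 0.5), c(5.6, sg, 0.5)), 0.13, "-Gdm"),
    mixU20_Gdm = mk("mixU20_Gdm",
                    list(c(3.6, sg, 0.25), c(4.4, sg, 0.50),
                         c(5.2, sg, 0.25)), 0.23, "++Gdm 40 mM")
  )
}

#' Ground-truth distance distribution of a scenario
#'
#' @param config a [preset()] scenario.
#' @param r_grid distance grid.
#' @return a [distance_distribution()].
#' @export
scenario_distribution <- function(config, r_grid = default_distance_grid()) {
  stopifnot(inherits(config, "scenario_config"))
  if (isTRUE(config$broad)) {
    flat_distribution(3, 6, r_grid)
  } else {
    gaussian_mixture(config$components, r_grid)
  }
}

#' Generate a synthetic dipolar trace for a scenario
#'
#' Builds the ground-truth P(r), simulates the noiseless trace through
#' the forward model (form factor at the scenario's modulation depth plus
#' homogeneous background), adds seeded white Gaussian noise, and
#' optionally writes the trace file and a manifest entry holding all
#' ground truth.
#'
#' @param config a [preset()] scenario (fields may be overridden before
#'   the call).
#' @param dir output directory; if NULL nothing is written.
#' @param seed overrides `config$seed`.
#' @param noise_sigma overrides `config$noise_sigma`.
#' @param r_grid distance grid for the ground truth.
#' @return list with `trace` ([dipolar_trace()]), `truth`
#'   ([distance_distribution()]), `config`, and (if written) `path`,
#'   `manifest`.
#' @export
generate_scenario <- function(config, dir = NULL, seed = NULL,
                              noise_sigma = NULL,
                              r_grid = default_distance_grid()) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(noise_sigma)) config$noise_sigma <- noise_sigma
  P <- scenario_distribution(config, r_grid)
  t_grid <- default_time_grid(config$t_max, config$dt)
  K <- kernel_matrix(t_grid, r_grid)
  FF <- form_factor(P, config$lambda_true, K)
  B <- background_model(config$background_rate, 3)
  tr <- apply_background(FF, B, meta = list(
    label = config$label, scenario = config$name,
    lambda_true = config$lambda_true,
    background_rate = config$background_rate))
  tr <- add_noise(tr, config$noise_sigma, seed = config$seed)
  out <- list(trace = tr, truth = P, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    path <- file.path(dir, paste0(config$name, ".dat"))
    write_trace(tr, path)
    manifest <- file.path(dir, "manifest.txt")
    comp_str <- if (isTRUE(config$broad)) "broad 3-6 nm" else {
      paste(vapply(config$components, function(cmp) {
        sprintf("%.3g/%.3g/%.3g", cmp[1], cmp[2], cmp[3])
      }, character(1)), collapse = "; ")
    }
    entry <- sprintf(
      "%s: components[mean/sigma/area nm]=%s lambda=%.4g rate=%.4g sigma=%.4g seed=%d file=%s",
      config$name, comp_str, config$lambda_true, config$background_rate,
      config$noise_sigma, config$seed, basename(path))
    cat(entry, "\n", sep = "", file = manifest, append = TRUE)
    out$path <- path
    out$manifest <- manifest
  }
  out
}

#' Generate the full scenario catalogue
#'
#' @param dir output directory for trace files plus a manifest.
#' @param seed top-level seed; per-scenario seeds are derived
#'   deterministically from it.
#' @return named list of [generate_scenario()] results.
#' @export
generate_catalogue <- function(dir = NULL, seed = 1L) {
  names_ <- preset_names()
  out <- list()
  for (i in seq_along(names_)) {
    cfg <- preset(names_[i])
    out[[names_[i]]] <- generate_scenario(cfg, dir = dir,
                                          seed = split_seed(seed, i))
  }
  out
}

# deterministic per-stage seed derivation, kept below 2^31
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}

#' Placeholder construct sequences
#'
#' The experimental construct sequences live in supplementary material
#' that is not shipped; these placeholders have the correct lengths
#' (23 nt) and carry the labeled uridines at the construct positions
#' (U14 for the P2 hairpin analogue; U18 and U20 for P1 duplex
#' analogues), with an A at the mirror position so both duplex strands
#' carry a U at the same strand position. They are synthetic stand-ins,
#' not the published sequences.
#'
#' @param name one of "P1_U18", "P1_U20", "P2_U14".
#' @return character RNA sequence.
#' @export
placeholder_sequence <- function(name = c("P1_U18", "P1_U20", "P2_U14")) {
  name <- match.arg(name)
  #         1234567890123456789012 3
  switch(name,
    # duplex-forming 23-mers: position 6 / 4 / 10 = A so that the
    # reverse complement carries U at 18 / 20 / 14
    P1_U18 = "GGCGCACGGCUCGGAGCUCCGGC",
    P1_U20 = "GGCACGGCUCGGAGGCCCGUGGC",
    P2_U14 = "GGCGCGGGCAGGCUCGAGCCCGC"
  )
}
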