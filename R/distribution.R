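#' Distance distribution P(r)
#'
#' Probability density over inter-label distance on a uniform, ascending
#' grid. Densities are non-negative and the trapezoidal integral is
#' normalized to 1 (unless the density is identically zero).
#'
#' @param r_grid distances in nm, uniform and ascending.
#' @param density non-negative density values, per nm.
#' @param normalize renormalize to unit trapezoidal integral (default TRUE).
#' @return object of class `distance_distribution` with fields `r_grid`,
#'   `density`.
#' @export
distance_distribution <- function(r_grid, density, normalize = TRUE) {
  if (length(r_grid) != length(density)) {
    stop("`r_grid` and `density` must have the same length")
  }
  if (length(r_grid) < 2) stop("grid must have at least 2 points")
  dr <- diff(r_grid)
  if (any(dr <= 0)) stop("`r_grid` must be strictly ascending")
  if (any(abs(dr - dr[1]) > 1e-8 * dr[1])) {
    stop("`r_grid` must be uniform")
  }
  if (any(!is.finite(density)) || any(density < -1e-12)) {
    stop("densities must be finite and non-negative")
  }
  density[density < 0] <- 0
  if (normalize) {
    z <- trapz(r_grid, density)
    if (z > 0) density <- density / z
  }
  structure(list(r_grid = r_grid, density = density),
            class = "distance_distribution")
}

#' Trapezoidal integral
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Gaussian mixture distance distribution
#'
#' Convenience constructor: a sum of Gaussian components (truncated to the
#' grid, renormalized).
#'
#' @param components list of `c(mean, sigma, area)` triplets (nm, nm,
#'   fraction); areas are renormalized to sum to 1.
#' @param r_grid distance grid in nm.
#' @return a [distance_distribution()].
#' @export
gaussian_mixture <- function(components, r_grid = default_distance_grid()) {
  if (length(components) == 0) stop("need at least one component")
  areas <- vapply(components, function(cmp) cmp[3], numeric(1))
  areas <- areas / sum(areas)
  dens <- rep(0, length(r_grid))
  for (i in seq_along(components)) {
    cmp <- components[[i]]
    dens <- dens + areas[i] * stats::dnorm(r_grid, cmp[1], cmp[2])
  }
  distance_distribution(r_grid, dens)
}

#' Flat (broad) distance distribution
#'
#' Uniform density between `r_lo` and `r_hi`, used to emulate a
#' conformationally heterogeneous ("broad") sample.
#'
#' @param r_lo,r_hi support limits in nm.
#' @param r_grid distance grid.
#' @return a [distance_distribution()].
#' @export
flat_distribution <- function(r_lo = 3, r_hi = 6,
                              r_grid = default_distance_grid()) {
  dens <- as.numeric(r_grid >= r_lo & r_grid <= r_hi)
  distance_distribution(r_grid, dens)
}

#' Peak detection on a distance distribution
#'
#' Local maxima above a height threshold, positions refined by 3-point
#' parabolic interpolation, sorted by position.
#'
#' @param P a [distance_distribution()].
#' @param min_height threshold as a fraction of the global maximum, in
#'   (0, 1\]; default 0.1.
#' @return data.frame with columns `position` (nm) and `height` (per nm);
#'   zero rows if no peak exceeds the threshold.
#' @export
find_peaks <- function(P, min_height = 0.1) {
  stopifnot(inherits(P, "distance_distribution"))
  if (min_height <= 0 || min_height > 1) stop("`min_height` must be in (0, 1]")
  y <- P$density
  r <- P$r_grid
  n <- length(y)
  thr <- min_height * max(y)
  pos <- numeric(0)
  hgt <- numeric(0)
  if (max(y) <= 0) {
    return(data.frame(position = pos, height = hgt))
  }
  for (i in 2:(n - 1)) {
    if (y[i] >= thr && y[i] > y[i - 1] && y[i] > y[i + 1]) {
      # parabolic refinement through (i-1, i, i+1)
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      if (denom < 0) {
        delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
        delta <- max(-0.5, min(0.5, delta))
      } else {
        delta <- 0
      }
      dr <- r[2] - r[1]
      pos <- c(pos, r[i] + delta * dr)
      hgt <- c(hgt, y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
    }
  }
  ord <- order(pos)
  data.frame(position = pos[ord], height = hgt[ord])
}

#' Wasserstein-1 distance between two distance distributions
#'
#' Integral of the absolute difference of the CDFs; used to score
#' forward-inverse consistency in nm.
#'
#' @param P1,P2 [distance_distribution()] objects on the same grid.
#' @return non-negative scalar in nm.
#' @export
wasserstein1 <- function(P1, P2) {
  stopifnot(inherits(P1, "distance_distribution"),
            inherits(P2, "distance_distribution"))
  if (length(P1$r_grid) != length(P2$r_grid) ||
      any(abs(P1$r_grid - P2$r_grid) > 1e-9)) {
    stop("distributions must share a grid")
  }
  r <- P1$r_grid
  dr <- r[2] - r[1]
  cdf <- function(p) cumsum((p[-1] + p[-length(p)]) / 2 * dr)
  sum(abs(cdf(P1$density) - cdf(P2$density))) * dr
}

#' @export
print.distance_distribution <- function(x, ...) {
  pk <- find_peaks(x, 0.2)
  cat(sprintf("<distance_distribution> %d pts, %.2f..%.2f nm",
              length(x$r_grid), min(x$r_grid), max(x$r_grid)))
  if (nrow(pk) > 0) {
    cat(sprintf("; peaks at %s nm", paste(sprintf("%.2f", pk$position),
                                          collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Write / read a distance distribution as two-column text
#'
#' Plain-text format: `#`-prefixed header lines (`# key: value`), then
#' whitespace-separated columns r (nm), density (per nm), and optionally
#' lower/upper uncertainty-band columns.
#'
#' @param P a [distance_distribution()].
#' @param path output file.
#' @param header named list written as `# key: value` lines.
#' @param band optional list with `lower`, `upper` vectors.
#' @return `path`, invisibly (writer); a `distance_distribution` with
#'   attributes `header` and `band` (reader).
#' @export
write_distribution <- function(P, path, header = list(), band = NULL) {
  stopifnot(inherits(P, "distance_distribution"))
  lines <- sprintf("# %s: %s", names(header),
                   vapply(header, format_header_value, character(1)))
  cols <- cbind(P$r_grid, P$density)
  if (!is.null(band)) cols <- cbind(cols, band$lower, band$upper)
  body <- apply(cols, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = " ")
  })
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  parsed <- read_headered_table(path)
  tab <- parsed$table
  if (ncol(tab) < 2) stop("distribution file needs >= 2 columns: ", path)
  P <- distance_distribution(tab[, 1], tab[, 2], normalize = FALSE)
  attr(P, "header") <- parsed$header
  if (ncol(tab) >= 4) {
    attr(P, "band") <- list(lower = tab[, 3], upper = tab[, 4])
  }
  P
}

format_header_value <- function(v) {
  if (is.numeric(v)) paste(sprintf("%.15g", v), collapse = " ")
  else paste(as.character(v), collapse = " ")
}

# shared reader for `# key: value` headered numeric tables; tolerates
# comma or whitespace delimiters in the body
read_headered_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_head <- grepl("^\\s*#", lines)
  header <- list()
  for (h in lines[is_head]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) header[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!is_head & nzchar(trimws(lines))]
  if (length(body) == 0) stop("no data rows in ", path)
  rows <- lapply(body, function(ln) {
    as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1]])
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1) stop("ragged rows in ", path)
  tab <- do.call(rbind, rows)
  if (any(!is.finite(tab))) stop("non-numeric data in ", path)
  list(header = header, table = tab)
}
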