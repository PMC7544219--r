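#' Zero-time alignment of a raw dipolar trace
#'
#' Places t = 0 at the maximum of the time trace, refining the discrete
#' maximum by a 3-point parabolic fit, and rescales the intensities so
#' that V(0) = 1. The trace is then linearly re-interpolated onto a
#' uniform grid starting at 0 with the original step, so downstream
#' operations see a canonical grid.
#'
#' @param raw a [dipolar_trace()]; needs at least 5 points.
#' @return an aligned [dipolar_trace()] with `meta$t0` recording the shift.
#' @export
align_zero_time <- function(raw) {
  stopifnot(inherits(raw, "dipolar_trace"))
  t <- raw$t_grid
  v <- raw$values
  if (length(t) < 5) stop("trace needs at least 5 points")
  if (diff(range(v)) < .Machine$double.eps * max(abs(v), 1)) {
    stop("degenerate all-constant trace: no maximum to align to")
  }
  # light running-mean smoothing so noise spikes cannot capture the
  # maximum, then a local least-squares parabola for sub-sample t0 and a
  # noise-robust peak value (a single noisy sample used for V(0) would
  # propagate as a 1/lambda-amplified offset into the rescaled signal)
  n <- length(v)
  half <- 2L
  vs <- vapply(seq_len(n), function(i) {
    mean(v[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  i <- which.max(vs)
  win <- max(1, i - 3):min(n, i + 3)
  cf <- stats::lm.fit(cbind(1, t[win] - t[i], (t[win] - t[i])^2),
                      v[win])$coefficients
  if (i == 1 || i == n) {
    warning("trace maximum at the boundary; zero time set there without refinement")
    t0 <- t[i]
  } else if (is.finite(cf[3]) && cf[3] < 0) {
    dt <- t[i + 1] - t[i]
    t0 <- t[i] + max(-dt / 2, min(dt / 2, -cf[2] / (2 * cf[3])))
  } else {
    t0 <- t[i]
  }
  v0 <- sum(cf * c(1, t0 - t[i], (t0 - t[i])^2))
  if (!is.finite(v0) || v0 <= 0) v0 <- v[i]
  ts <- t - t0
  dt <- stats::median(diff(t))
  grid <- seq(0, max(ts), by = dt)
  vals <- stats::approx(ts, v / v0, xout = grid, rule = 1)$y
  meta <- raw$meta
  meta$t0 <- t0
  dipolar_trace(grid, vals, meta = meta)
}

#' Merge traces recorded at different frequency offsets
#'
#' Point-wise mean of normalized, aligned traces, interpolated onto the
#' first trace's grid (restricted to the overlap of all traces). Summing
#' traces recorded at several pump-detection offsets removes the
#' orientation selectivity of a rigid label; averaging over
#' \eqn{\tau}-incremented traces additionally suppresses deuterium ESEEM.
#'
#' @param traces non-empty list of aligned [dipolar_trace()] objects.
#' @return merged [dipolar_trace()]; `meta$merged_offsets` lists the
#'   offset tags of the inputs.
#' @export
merge_offset_traces <- function(traces) {
  if (!is.list(traces) || length(traces) == 0) {
    stop("`traces` must be a non-empty list of dipolar traces")
  }
  lapply(traces, function(x) stopifnot(inherits(x, "dipolar_trace")))
  t_lo <- max(vapply(traces, function(x) min(x$t_grid), numeric(1)))
  t_hi <- min(vapply(traces, function(x) max(x$t_grid), numeric(1)))
  if (t_lo >= t_hi) stop("traces have non-overlapping time ranges")
  grid <- traces[[1]]$t_grid
  grid <- grid[grid >= t_lo & grid <= t_hi]
  if (length(grid) < 2) stop("overlap region too short to merge")
  vals <- vapply(traces, function(x) {
    stats::approx(x$t_grid, x$values, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  offsets <- vapply(traces, function(x) {
    if (is.null(x$meta$offset)) NA_character_ else as.character(x$meta$offset)
  }, character(1))
  meta <- traces[[1]]$meta
  meta$offset <- NULL
  meta$merged_offsets <- offsets
  dipolar_trace(grid, rowMeans(vals), meta = meta)
}

#' Background correction and modulation-depth estimation
#'
#' Fits the homogeneous background \eqn{s \exp(-k t^{d/3})} to the tail of
#' an aligned trace (from `fit_start * t_max` to `t_max`), divides it out,
#' renormalizes to F(0) = 1 and reads the modulation depth
#' \eqn{\lambda = 1 - } mean of the corrected form factor over the fit
#' window.
#'
#' @param trace aligned, normalized [dipolar_trace()].
#' @param fit_start start of the fit window as a fraction of the trace
#'   length, in (0, 0.9); default 1/3 (fit on the final two thirds).
#' @param dim background dimensionality, fixed at 3 (homogeneous solution)
#'   unless overridden.
#' @return list with `background` ([background_model()]), `form_factor`
#'   ([form_factor()]) and `depth` (the \eqn{\lambda} estimate, carrying a
#'   `percent` attribute).
#' @export
fit_background <- function(trace, fit_start = 1 / 3, dim = 3) {
  stopifnot(inherits(trace, "dipolar_trace"))
  if (fit_start <= 0 || fit_start >= 0.9) stop("`fit_start` must be in (0, 0.9)")
  t <- trace$t_grid
  v <- trace$values
  t_max <- max(t)
  win <- t >= fit_start * t_max
  if (sum(win) < 5) stop("background fit window has fewer than 5 points")
  tw <- t[win]
  vw <- v[win]
  # linearized fit: log v = log s - k t^(d/3); requires positive tail
  pos <- vw > 0
  if (sum(pos) < 5) stop("trace tail not positive; cannot fit log-linear background")
  x <- tw[pos]^(dim / 3)
  fit <- stats::lm.fit(cbind(1, -x), log(vw[pos]))
  k <- fit$coefficients[2]
  s <- exp(fit$coefficients[1])
  # refine on the linear scale
  nl <- try(stats::optim(
    c(log_s = log(s), k = k),
    function(p) sum((vw - exp(p[1]) * exp(-p[2] * tw^(dim / 3)))^2),
    method = "Nelder-Mead"
  ), silent = TRUE)
  if (!inherits(nl, "try-error") && is.finite(nl$value)) {
    s <- exp(nl$par[1])
    k <- nl$par[2]
  }
  if (!is.finite(k) || k < 0) {
    warning("background rate fit went negative; clamping to 0")
    k <- 0
    s <- mean(vw)
  }
  B <- background_model(unname(k), dim)
  Fv <- v / background_decay(B, t)
  Fv <- Fv / Fv[which.min(abs(t))]
  FF <- structure(list(t_grid = t, values = Fv, depth = NA_real_),
                  class = "form_factor")
  depth <- 1 - mean(Fv[win])
  depth <- max(0, min(1, depth))
  FF$depth <- depth
  attr(depth, "percent") <- round_half_up(100 * depth)
  list(background = B, form_factor = FF, depth = depth)
}

#' Modulation depth of a corrected form factor
#'
#' \eqn{\lambda = 1 -} mean of F over the final 20 % of the time window,
#' i.e. the depth read off the plateau of the background-corrected trace.
#'
#' @param F a normalized [form_factor()].
#' @return depth as a fraction in \[0, 1\] with attribute `percent`
#'   (rounded half-up to the nearest integer).
#' @export
modulation_depth <- function(F) {
  stopifnot(inherits(F, "form_factor"))
  t <- F$t_grid
  win <- t >= max(t) - 0.2 * (max(t) - min(t))
  if (sum(win) < 5) stop("final-20% window has fewer than 5 points")
  depth <- 1 - mean(F$values[win])
  depth <- max(0, min(1, depth))
  attr(depth, "percent") <- round_half_up(100 * depth)
  depth
}

# round-half-up to match the reporting convention for percentages
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Write a corrected form factor as two-column text
#'
#' @param F a [form_factor()].
#' @param path file path.
#' @param header named list (lambda, fit_start, background parameters, ...).
#' @return `path` invisibly.
#' @export
write_form_factor <- function(F, path, header = list()) {
  stopifnot(inherits(F, "form_factor"))
  header <- c(list(lambda = F$depth), header)
  lines <- sprintf("# %s: %s", names(header),
                   vapply(header, format_header_value, character(1)))
  body <- sprintf("%.17g %.17g", F$t_grid, F$values)
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname write_form_factor
#' @export
read_form_factor <- function(path) {
  parsed <- read_headered_table(path)
  tab <- parsed$table
  if (ncol(tab) != 2) stop("form-factor file needs exactly 2 columns: ", path)
  lambda <- parsed$header$lambda
  if (is.null(lambda)) {
    stop("form-factor file is missing the `lambda` header field: ", path)
  }
  structure(list(t_grid = tab[, 1], values = tab[, 2],
                 depth = as.numeric(lambda)),
            class = "form_factor")
}
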