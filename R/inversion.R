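#' Non-negative Tikhonov inversion of a form factor
#'
#' Recovers the distance distribution from a background-corrected form
#' factor by solving
#' \deqn{\hat P = \arg\min_{P \ge 0} \|K P - S\|^2 + \alpha^2 \|L_2 P\|^2,}
#' where \eqn{S = (F - (1 - \lambda)) / \lambda} is the rescaled dipolar
#' evolution, \eqn{L_2} the second-difference operator (reflected at the
#' grid ends) and \eqn{\alpha} the regularization parameter. The
#' modulation depth \eqn{\lambda} is held fixed (estimated upstream by
#' [fit_background()]), matching a two-stage workflow. Non-negativity is
#' enforced through an active-set NNLS solve on the stacked system, never
#' by clipping.
#'
#' @param F a [form_factor()] with a known `depth`.
#' @param K a [kernel_matrix()] on a matching time grid.
#' @param alpha positive regularization parameter.
#' @return object of class `inversion_result`: `distribution`
#'   ([distance_distribution()]), `alpha`, `residual_norm`, `seminorm`,
#'   `diagnostics`.
#' @export
tikhonov_solve <- function(F, K, alpha) {
  stopifnot(inherits(F, "form_factor"), inherits(K, "dipolar_kernel"))
  if (!is.finite(alpha) || alpha < 0) stop("`alpha` must be >= 0")
  lambda <- F$depth
  if (is.null(lambda) || !is.finite(lambda) || lambda <= 0) {
    stop("form factor must carry a positive modulation depth")
  }
  if (length(F$t_grid) != length(K$t_grid) ||
      any(abs(F$t_grid - K$t_grid) > 1e-6)) {
    stop("form factor and kernel time grids do not match")
  }
  if (alpha == 0) {
    warning("alpha = 0: unregularized NNLS on an ill-conditioned kernel")
  }
  S <- (F$values - (1 - lambda)) / lambda
  r <- K$r_grid
  n <- length(r)
  dr <- r[2] - r[1]
  w <- rep(dr, n)
  w[c(1, n)] <- dr / 2
  A <- sweep(K$values, 2, w, `*`)
  L <- second_difference_operator(n)
  As <- rbind(A, alpha * L)
  bs <- c(S, rep(0, n))
  sol <- nnls_solve(As, bs)
  if (!isTRUE(sol$converged)) {
    warning("NNLS did not fully converge; returning best iterate")
  }
  x <- sol$x
  resid <- sqrt(sum((A %*% x - S)^2))
  semin <- sqrt(sum((L %*% x)^2))
  P <- distance_distribution(r, x, normalize = TRUE)
  structure(list(distribution = P, alpha = alpha, residual_norm = resid,
                 seminorm = semin, diagnostics = NULL),
            class = "inversion_result")
}

# n x n second-difference operator with reflection (Neumann) ends
second_difference_operator <- function(n) {
  L <- matrix(0, n, n)
  for (i in 2:(n - 1)) L[i, (i - 1):(i + 1)] <- c(1, -2, 1)
  L[1, 1:2] <- c(-1, 1)
  L[n, (n - 1):n] <- c(1, -1)
  L
}

#' L-curve selection of the regularization parameter
#'
#' Runs [tikhonov_solve()] over a log-spaced alpha grid and returns the
#' alpha at the point of maximum curvature of the L-curve
#' (log residual norm vs log seminorm), ties broken toward the larger
#' (smoother) alpha. If the discrete curvature is degenerate (no interior
#' maximum), falls back to the corner found as the point closest to the
#' origin of the axis-normalized log-log curve, with a warning.
#'
#' @param F a [form_factor()].
#' @param K a [kernel_matrix()].
#' @param alpha_grid positive, log-spaced; at least 8 values spanning at
#'   least 4 decades (a single value is returned as-is with a warning).
#' @return selected alpha, with attribute `lcurve` (data.frame of alpha,
#'   residual_norm, seminorm, curvature) and attribute `result` (the
#'   `inversion_result` at the selected alpha).
#' @export
select_alpha_lcurve <- function(F, K, alpha_grid = default_alpha_grid()) {
  if (length(alpha_grid) == 1) {
    warning("single-alpha grid: returning it without L-curve selection")
    res <- tikhonov_solve(F, K, alpha_grid)
    out <- alpha_grid
    attr(out, "result") <- res
    return(out)
  }
  if (length(alpha_grid) < 8 ||
      log10(max(alpha_grid) / min(alpha_grid)) < 4) {
    stop("alpha grid must contain >= 8 values spanning >= 4 decades")
  }
  alpha_grid <- sort(alpha_grid)
  runs <- lapply(alpha_grid, function(a) tikhonov_solve(F, K, a))
  rho <- vapply(runs, function(x) x$residual_norm, numeric(1))
  eta <- vapply(runs, function(x) x$seminorm, numeric(1))
  # monotonicity sanity of the L-curve (tiny violations tolerated)
  if (any(diff(rho) < -1e-8 * max(rho))) {
    warning("residual norm not monotone in alpha; L-curve may be unreliable")
  }
  eps <- 1e-300
  lr <- log(rho + eps)
  le <- log(eta + eps)
  la <- log(alpha_grid)
  kappa <- lcurve_curvature(la, lr, le)
  interior <- 2:(length(alpha_grid) - 1)
  # the corner sits where the misfit is still near its floor; excluding
  # the steep over-smoothed branch suppresses spurious curvature kinks
  # introduced by the non-negativity constraint
  floor_lim <- max(1.2 * min(rho), min(rho) + 0.05 * diff(range(rho)))
  near_floor <- rho[interior] <= floor_lim
  k_int <- ifelse(near_floor, kappa[interior], NA_real_)
  if (all(!is.finite(k_int)) || max(k_int, na.rm = TRUE) <= 0) {
    warning("degenerate L-curve; falling back to normalized corner distance")
    nr <- (lr - min(lr)) / max(diff(range(lr)), eps)
    ne <- (le - min(le)) / max(diff(range(le)), eps)
    best <- which.min(nr^2 + ne^2)
  } else {
    kmax <- max(k_int, na.rm = TRUE)
    cand <- interior[which(!is.na(k_int) & k_int >= kmax - 1e-12 * abs(kmax))]
    best <- max(cand)   # ties toward larger alpha
  }
  out <- alpha_grid[best]
  attr(out, "lcurve") <- data.frame(alpha = alpha_grid, residual_norm = rho,
                                    seminorm = eta, curvature = kappa)
  attr(out, "result") <- runs[[best]]
  out
}

# signed curvature of the parametric curve (lr(la), le(la)) by central
# finite differences; endpoints NA
lcurve_curvature <- function(la, lr, le) {
  d1 <- function(y) {
    n <- length(y)
    c(NA, (y[3:n] - y[1:(n - 2)]) / (la[3:n] - la[1:(n - 2)]), NA)
  }
  d2 <- function(y) {
    n <- length(y)
    h1 <- la[2:(n - 1)] - la[1:(n - 2)]
    h2 <- la[3:n] - la[2:(n - 1)]
    c(NA, 2 * (h1 * y[3:n] - (h1 + h2) * y[2:(n - 1)] + h2 * y[1:(n - 2)]) /
        (h1 * h2 * (h1 + h2)), NA)
  }
  xp <- d1(lr); yp <- d1(le)
  xpp <- d2(lr); ypp <- d2(le)
  (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
}

#' Default regularization-parameter grid
#'
#' 16 alphas, log-spaced over 1e-3 to 1e3 relative to the unit-scale
#' discretized kernel.
#'
#' @param n number of grid points.
#' @param lo,hi decade limits.
#' @return numeric vector.
#' @export
default_alpha_grid <- function(n = 16, lo = 1e-3, hi = 1e3) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Background-start validation of an inversion
#'
#' Repeats background correction and inversion (the full refined
#' pipeline, see [process_trace()]) for an ensemble of background
#' fit-start fractions and, in addition, for residual-bootstrap
#' replicates of the trace that represent the noise-sampling uncertainty
#' an fs-ensemble alone cannot express. The resulting distributions are
#' summarized as the mean curve plus a point-wise uncertainty band
#' (min/max envelope, or mean +/- 2 SD when >= 8 variants succeed). This
#' is the package's stand-in for the interactive validation tools of
#' conventional DEER software.
#'
#' @param trace aligned [dipolar_trace()].
#' @param start_grid at least 3 fit-start fractions in (0, 0.9).
#' @param r_grid distance grid for the inversion.
#' @param alpha_grid alpha grid for [select_alpha_lcurve()].
#' @param n_boot number of residual-bootstrap replicates (0 disables).
#' @param seed seed for the bootstrap resampling.
#' @return list with `distribution` (mean, a [distance_distribution()]),
#'   `lower`, `upper` (band vectors, per nm) and `n_variants`.
#' @export
validate_inversion <- function(trace,
                               start_grid = seq(0.25, 0.5, length.out = 5),
                               r_grid = default_distance_grid(),
                               alpha_grid = default_alpha_grid(),
                               n_boot = 8, seed = 1L) {
  stopifnot(inherits(trace, "dipolar_trace"))
  if (length(start_grid) < 3) stop("need at least 3 fit-start values")
  curves <- list()
  base_pr <- NULL
  for (fs in start_grid) {
    res <- try(suppressWarnings({
      pr <- process_trace(trace, fit_start = fs, r_grid = r_grid,
                          alpha_grid = alpha_grid)
      if (is.null(base_pr)) base_pr <- pr
      pr$distribution$density
    }), silent = TRUE)
    if (inherits(res, "try-error")) {
      warning(sprintf("validation variant fit_start = %.3g failed; skipped", fs))
    } else {
      curves[[length(curves) + 1]] <- res
    }
  }
  if (length(curves) == 0) stop("all validation variants failed")
  if (n_boot > 0 && !is.null(base_pr)) {
    # residual bootstrap around the fitted model
    al <- base_pr$trace
    model <- base_pr$form_factor$values *
      background_decay(base_pr$background, al$t_grid)
    model <- model * (al$values[1] / model[1])
    resid <- al$values - model
    boots <- withr_seed(seed, lapply(seq_len(n_boot), function(b) {
      sample(resid, length(resid), replace = TRUE)
    }))
    base_dens <- base_pr$distribution$density
    for (b in seq_len(n_boot)) {
      res <- try(suppressWarnings({
        trb <- dipolar_trace(al$t_grid, model + boots[[b]], meta = al$meta)
        process_trace(trb, r_grid = r_grid,
                      alpha_grid = alpha_grid)$distribution$density
      }), silent = TRUE)
      if (inherits(res, "try-error")) {
        warning(sprintf("bootstrap replicate %d failed; skipped", b))
      } else {
        curves[[length(curves) + 1]] <- res
        # the replicate's generating truth is the baseline estimate, so
        # base - replicate estimates the inversion bias; the reflected
        # curve folds that bias into the envelope (bootstrap bias
        # correction)
        curves[[length(curves) + 1]] <- pmax(2 * base_dens - res, 0)
      }
    }
  }
  M <- do.call(cbind, curves)
  mu <- rowMeans(M)
  lower <- apply(M, 1, min)
  upper <- apply(M, 1, max)
  if (ncol(M) >= 8) {
    # widen the min/max envelope to the 2 SD band where that is larger
    sdv <- apply(M, 1, stats::sd)
    lower <- pmax(0, pmin(lower, mu - 2 * sdv))
    upper <- pmax(upper, mu + 2 * sdv)
  }
  list(distribution = distance_distribution(r_grid, mu),
       lower = lower, upper = upper, n_variants = ncol(M))
}
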