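#' Predicted band fractions for cooperative two-site binding
#'
#' Equilibrium model for a DNA probe carrying two identical protein-dimer
#' binding sites. With applied dimer amount `p2`, the probe partitions into
#' free probe (y0), probe bound by one dimer (y2, i.e. two protein subunits)
#' and probe bound by two dimers (y4, four subunits):
#' \deqn{Z = 1 + \frac{2 p_2}{k_{d1}} + \frac{p_2^2}{k_{d1} k_{d2}}}
#' with \eqn{y_0 = 1/Z}, \eqn{y_2 = (2 p_2 / k_{d1})/Z},
#' \eqn{y_4 = (p_2^2/(k_{d1} k_{d2}))/Z}.
#' `kd1` is the dissociation constant of the first dimer binding an empty
#' probe, `kd2` that of the second dimer binding a half-occupied probe. Both
#' are in the (arbitrary, relative) units of `p2`.
#'
#' @param p2 numeric vector of non-negative applied protein amounts.
#' @param kd1,kd2 positive dissociation constants, same units as `p2`.
#' @return data.frame with columns `p2`, `y0`, `y2`, `y4`; rows sum to 1.
#' @examples
#' predict_fractions(1, kd1 = 1, kd2 = 1)   # 0.25, 0.50, 0.25
#' @export
predict_fractions <- function(p2, kd1, kd2) {
  check_scalar_pos(kd1, "kd1")
  check_scalar_pos(kd2, "kd2")
  if (!is.numeric(p2) || any(!is.finite(p2)) || any(p2 < 0)) {
    stop("`p2` must be finite and non-negative", call. = FALSE)
  }
  z  <- 1 + 2 * p2 / kd1 + p2^2 / (kd1 * kd2)
  y2 <- (2 * p2 / kd1) / z
  y4 <- (p2^2 / (kd1 * kd2)) / z
  data.frame(p2 = p2, y0 = 1 / z, y2 = y2, y4 = y4)
}

#' Cooperativity constant
#'
#' The ratio \eqn{k_{coop} = k_{d1}/k_{d2}}: 1 for independent (non-
#' cooperative) binding of the two dimers, values well above 1 when the
#' second dimer binds more tightly than the first, i.e. when the protein
#' tetramerizes on DNA. Because `kd1` and `kd2` share the (unknown, relative)
#' protein units, their ratio is a well-defined dimensionless quantity even
#' when absolute concentrations are not.
#'
#' @param kd1,kd2 positive dissociation constants in common units.
#' @return dimensionless cooperativity constant.
#' @export
cooperativity <- function(kd1, kd2) {
  check_scalar_pos(kd1, "kd1")
  check_scalar_pos(kd2, "kd2")
  kd1 / kd2
}

#' Assemble an EMSA titration series
#'
#' One gel: lanes with increasing applied protein against a constant amount
#' of a two-site probe, each lane quantified into the three band fractions.
#' Measured fractions are renormalized to sum exactly to 1 per lane provided
#' the raw sum is within `renorm_tol` of 1; lanes further off are rejected.
#'
#' @param applied_protein non-negative protein amounts (arbitrary units),
#'   at most one zero.
#' @param frac_free,frac_one_dimer,frac_two_dimers band fractions in
#'   \[0, 1\] per lane (free probe, probe + one dimer, probe + two dimers).
#' @param label,probe_id free-text identifiers.
#' @param renorm_tol maximum tolerated deviation of a lane's fraction sum
#'   from 1 before renormalization (default 0.05).
#' @return object of class `titration_series` (a data.frame with one row
#'   per lane and columns `lane`, `applied_protein`, `frac_free`,
#'   `frac_one_dimer`, `frac_two_dimers`).
#' @export
titration_series <- function(applied_protein, frac_free, frac_one_dimer,
                             frac_two_dimers, label = "", probe_id = "",
                             renorm_tol = 0.05) {
  n <- length(applied_protein)
  if (n == 0L) stop("empty titration series", call. = FALSE)
  stopifnot(length(frac_free) == n, length(frac_one_dimer) == n,
            length(frac_two_dimers) == n)
  if (any(!is.finite(applied_protein)) || any(applied_protein < 0)) {
    stop("applied_protein must be finite and non-negative", call. = FALSE)
  }
  if (sum(applied_protein == 0) > 1) {
    stop("at most one zero-protein lane is allowed", call. = FALSE)
  }
  fr <- cbind(frac_free, frac_one_dimer, frac_two_dimers)
  if (any(!is.finite(fr)) || any(fr < -1e-12) || any(fr > 1 + 1e-12)) {
    stop("band fractions must lie in [0, 1]", call. = FALSE)
  }
  fr <- pmin(pmax(fr, 0), 1)
  s <- rowSums(fr)
  off <- abs(s - 1) > renorm_tol
  if (any(off)) {
    stop(sprintf("lane(s) %s: fraction sums deviate from 1 by more than %g",
                 paste(which(off), collapse = ", "), renorm_tol),
         call. = FALSE)
  }
  renorm <- abs(s - 1) > 1e-9   # leave model-exact lanes bitwise untouched
  fr[renorm, ] <- fr[renorm, , drop = FALSE] / s[renorm]
  out <- data.frame(lane = seq_len(n), applied_protein = applied_protein,
                    frac_free = fr[, 1], frac_one_dimer = fr[, 2],
                    frac_two_dimers = fr[, 3])
  structure(out, label = label, probe_id = probe_id,
            class = c("titration_series", "data.frame"))
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("EMSA titration series '%s' (probe '%s'): %d lanes\n",
              attr(x, "label"), attr(x, "probe_id"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# residuals of the three fraction curves at all lanes, theta = log10(kd1, kd2)
.coop_resid <- function(theta, series) {
  pred <- predict_fractions(series$applied_protein,
                            kd1 = 10^theta[1], kd2 = 10^theta[2])
  c(series$frac_free - pred$y0,
    series$frac_one_dimer - pred$y2,
    series$frac_two_dimers - pred$y4)
}

#' Fit the cooperative two-site binding model to a titration series
#'
#' Joint nonlinear least squares of the three band-fraction curves
#' (see [predict_fractions()]) over all lanes, with equal weights.
#' Optimization is over `log10(kd1)` and `log10(kd2)` (Levenberg-Marquardt,
#' [minpack.lm::nls.lm()]), multi-started from a 3 x 3 grid spanning the
#' observed protein-amount range to guard against local minima. The best
#' (lowest-RSS) start is reported.
#'
#' Censoring: EMSA setups cannot resolve arbitrarily strong cooperativity
#' because the intermediate (one-dimer) band vanishes. If the fitted
#' one-dimer fraction never exceeds the detection threshold `delta` at any
#' observed lane, or the fitted cooperativity exceeds `ceiling`, the fit is
#' reported censored with `kcoop` set to `ceiling`, to be read as a lower
#' bound.
#'
#' @param series a [titration_series()] with >= 3 distinct positive protein
#'   amounts.
#' @param ceiling largest determinable cooperativity (default 200).
#' @param delta detection threshold for the intermediate band (default 0.02).
#' @return object of class `cooperative_fit`: list with `kd1`, `kd2`,
#'   `kcoop`, `censored`, `ceiling`, `rss`, `converged`, plus diagnostics.
#' @export
fit_cooperative <- function(series, ceiling = 200, delta = 0.02) {
  stopifnot(inherits(series, "titration_series"))
  check_scalar_pos(ceiling, "ceiling")
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta >= 1) {
    stop("`delta` must be a single value in [0, 1)", call. = FALSE)
  }
  pos <- series$applied_protein > 0
  if (length(unique(series$applied_protein)) < 3 || sum(pos) < 3) {
    stop("need at least 3 lanes with distinct positive protein amounts",
         call. = FALSE)
  }
  if (all(series$frac_one_dimer + series$frac_two_dimers == 0)) {
    stop("degenerate series: no bound probe in any lane", call. = FALSE)
  }

  rng <- range(series$applied_protein[pos])
  starts <- log10(exp(seq(log(rng[1]), log(rng[2]), length.out = 3)))
  grid <- expand.grid(l1 = starts, l2 = starts)

  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(grid[i, ]), fn = .coop_resid,
                         series = series,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-14) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("optimizer failed from every start", call. = FALSE)
  }
  kd1 <- 10^best$fit$par[1]
  kd2 <- 10^best$fit$par[2]
  kcoop_raw <- kd1 / kd2
  # MINPACK info 1-3: ftol/xtol convergence; 4: gradient orthogonal to
  # residual (holds trivially at a perfect fit), also accepted
  converged <- best$fit$info %in% 1:4

  fitted_y2 <- predict_fractions(series$applied_protein, kd1, kd2)$y2
  censored <- max(fitted_y2) < delta || kcoop_raw > ceiling

  structure(list(
    kd1 = kd1, kd2 = kd2,
    kcoop = if (censored) ceiling else kcoop_raw,
    kcoop_raw = kcoop_raw,
    censored = censored, ceiling = ceiling, delta = delta,
    rss = best$rss, converged = converged,
    n_lanes = nrow(series), info = best$fit$info,
    message = best$fit$message, label = attr(series, "label")
  ), class = "cooperative_fit")
}

#' @export
print.cooperative_fit <- function(x, ...) {
  cat("Cooperative two-site binding fit\n")
  cat(sprintf("  kd1 = %.4g, kd2 = %.4g (relative units)\n", x$kd1, x$kd2))
  if (x$censored) {
    cat(sprintf("  kcoop >= %.4g (censored at ceiling; raw estimate %.4g)\n",
                x$ceiling, x$kcoop_raw))
  } else {
    cat(sprintf("  kcoop = %.4g\n", x$kcoop))
  }
  cat(sprintf("  rss = %.3g over %d lanes; converged: %s\n",
              x$rss, x$n_lanes, x$converged))
  invisible(x)
}

#' Single-site saturation binding curve
#'
#' Hyperbolic binding of a fixed amount of protein `pt` to increasing free
#' probe `d_free`: bound complex \eqn{[PD] = P_t [D] / (k_d + [D])},
#' the rearrangement of \eqn{k_d = ([P_t]-[PD])[D]/[PD]}.
#'
#' @param d_free non-negative free (unbound) probe amounts.
#' @param pt positive total protein, same units as the complex.
#' @param kd positive dissociation constant in probe units.
#' @return predicted bound complex, same length as `d_free`.
#' @export
predict_saturation <- function(d_free, pt, kd) {
  check_scalar_pos(pt, "pt")
  check_scalar_pos(kd, "kd")
  if (!is.numeric(d_free) || any(!is.finite(d_free)) || any(d_free < 0)) {
    stop("`d_free` must be finite and non-negative", call. = FALSE)
  }
  pt * d_free / (kd + d_free)
}

#' Assemble a saturation binding series
#'
#' @param free_probe non-negative free probe amounts (the independent
#'   variable of the saturation model).
#' @param bound non-negative amounts of protein-DNA complex.
#' @param label free text.
#' @return object of class `saturation_series` (a data.frame).
#' @export
saturation_series <- function(free_probe, bound, label = "") {
  stopifnot(length(free_probe) == length(bound))
  if (any(!is.finite(free_probe)) || any(free_probe < 0) ||
      any(!is.finite(bound)) || any(bound < 0)) {
    stop("free_probe and bound must be finite and non-negative",
         call. = FALSE)
  }
  structure(data.frame(free_probe = free_probe, bound = bound),
            label = label, class = c("saturation_series", "data.frame"))
}

#' Total-probe to free-probe conversion
#'
#' Convenience for assays where the applied (total) probe is known rather
#' than the unbound fraction: free = total - bound.
#'
#' @param total_probe applied probe amounts.
#' @param bound measured complex amounts (<= total).
#' @return numeric vector of free probe amounts.
#' @export
free_probe_from_total <- function(total_probe, bound) {
  if (any(bound > total_probe + 1e-12)) {
    stop("bound exceeds total probe", call. = FALSE)
  }
  pmax(total_probe - bound, 0)
}

#' Fit the single-site saturation model
#'
#' Least-squares estimates of total protein `pt` and dissociation constant
#' `kd` in [predict_saturation()], optimizing `log10(pt)`, `log10(kd)` by
#' Levenberg-Marquardt. A fit that runs into the small-`kd` boundary (a
#' series already saturated at every probe amount carries no information on
#' `kd`) is flagged with `converged = FALSE` and `boundary = TRUE`.
#'
#' @param series a [saturation_series()] with >= 3 points; a warning is
#'   issued if the points do not bracket the fitted half-saturation.
#' @return object of class `saturation_fit`: `kd`, `pt`, `rss`, `converged`,
#'   `boundary`.
#' @export
fit_saturation <- function(series) {
  stopifnot(inherits(series, "saturation_series"))
  if (nrow(series) < 3) stop("need at least 3 points", call. = FALSE)
  if (all(series$bound == 0)) {
    stop("degenerate series: bound signal is zero everywhere", call. = FALSE)
  }
  d <- series$free_probe
  b <- series$bound
  pt0 <- max(b) * 1.05
  half <- which.min(abs(b - pt0 / 2))
  kd0 <- max(d[half], min(d[d > 0]))
  resid_fn <- function(theta) b - predict_saturation(d, 10^theta[1], 10^theta[2])
  fit <- minpack.lm::nls.lm(
    par = log10(c(pt0, kd0)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  pt <- 10^fit$par[1]
  kd <- 10^fit$par[2]
  boundary <- kd < 1e-6 * max(d)
  converged <- (fit$info %in% 1:4) && !boundary
  if (kd < min(d[d > 0]) || kd > max(d)) {
    warning("fitted half-saturation lies outside the observed probe range",
            call. = FALSE)
  }
  structure(list(kd = kd, pt = pt, rss = sum(fit$fvec^2),
                 converged = converged, boundary = boundary,
                 info = fit$info, label = attr(series, "label")),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("Saturation binding fit\n")
  cat(sprintf("  kd = %.4g (probe units), pt = %.4g\n", x$kd, x$pt))
  cat(sprintf("  rss = %.3g; converged: %s%s\n", x$rss, x$converged,
              if (x$boundary) " (kd at boundary)" else ""))
  invisible(x)
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  invisible(TRUE)
}
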