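#' Default LexA molecular weight (Da)
#'
#' Monomer molecular weight used to convert a mass concentration of LexA
#' into a molar concentration when none is supplied explicitly.
#' @export
LEXA_MW <- 22358

#' Build a normalized cleavage time course
#'
#' One cleavage reaction condition: aliquot times, band intensities from
#' densitometry, and the fraction of uncleaved protein remaining, defined
#' as the ratio of each band intensity to the initial (t = 0) band. The
#' first fraction is exactly 1 by construction.
#'
#' @param times Minutes, non-negative, strictly increasing, at least 3.
#' @param intensities Densitometry units, non-negative; `intensities[1]`
#'   must be positive. Give either this or `fractions`.
#' @param fractions Pre-normalized fractions remaining (first element 1).
#' @param inhibitor_conc Inhibitor concentration, micromolar (0 = control).
#' @param lexa0 Initial protein concentration, micromolar (`NA` if unknown).
#' @param label Free-text condition label.
#' @return Object of class `timecourse`: list with `label`,
#'   `inhibitor_conc`, `lexa0`, `ratio` (inhibitor:protein molar ratio, NA
#'   when `lexa0` unknown), `times`, `intensities`, `fractions`.
#' @export
timecourse <- function(times, intensities = NULL, fractions = NULL,
                       inhibitor_conc = 0, lexa0 = NA_real_, label = "") {
  times <- as.numeric(times)
  if (length(times) < 3) stop("timecourse: at least 3 time points required")
  if (any(times < 0)) stop("timecourse: times must be non-negative")
  if (any(diff(times) <= 0)) stop("timecourse: times must be strictly increasing")
  if (is.null(fractions)) {
    if (is.null(intensities)) stop("timecourse: give intensities or fractions")
    intensities <- as.numeric(intensities)
    if (length(intensities) != length(times))
      stop("timecourse: times and intensities differ in length")
    if (any(intensities < 0)) stop("timecourse: negative intensity")
    if (intensities[1] <= 0)
      stop("unnormalizable: initial intensity must be positive")
    fractions <- intensities / intensities[1]
  } else {
    fractions <- as.numeric(fractions)
    if (length(fractions) != length(times))
      stop("timecourse: times and fractions differ in length")
    if (abs(fractions[1] - 1) > 1e-9)
      stop("timecourse: fractions must be normalized (first element 1)")
    if (is.null(intensities)) intensities <- fractions
  }
  ratio <- if (is.na(lexa0) || lexa0 <= 0) NA_real_ else inhibitor_conc / lexa0
  structure(list(label = label, inhibitor_conc = inhibitor_conc,
                 lexa0 = lexa0, ratio = ratio, times = times,
                 intensities = as.numeric(intensities), fractions = fractions),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse%s> %d points, 0-%g min, [I] = %g uM%s\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              length(x$times), max(x$times), x$inhibitor_conc,
              if (!is.na(x$ratio)) sprintf(", [I]:[LexA] = %g", x$ratio) else ""))
  invisible(x)
}

#' Normalize band intensities to fractions remaining
#'
#' Divides each band intensity by the initial (t = 0) band, the
#' normalization used when the uncleaved-protein band is tracked across
#' aliquots of one reaction.
#'
#' @inheritParams timecourse
#' @param ... Passed to [timecourse()] (condition metadata).
#' @return A `timecourse` with `fractions = intensities / intensities[1]`.
#' @examples
#' normalize_timecourse(c(0, 5, 10), c(100, 50, 25))$fractions # 1 0.5 0.25
#' @export
normalize_timecourse <- function(times, intensities, ...) {
  timecourse(times = times, intensities = intensities, ...)
}

#' Fit a first-order cleavage rate constant
#'
#' Least-squares fit of the integrated first-order rate law
#' f(t) = exp(-k t) to the fraction of protein remaining. The model has a
#' single parameter: normalization pins f(0) = 1, so no amplitude or
#' offset is floated. The fit is initialized from the through-origin
#' log-linear regression slope and k is constrained to be non-negative;
#' the standard error comes from the linearized (Gauss-Newton) covariance
#' and R-squared is computed on the fraction scale.
#'
#' @param tc A `timecourse`, or a numeric vector of times (with `fractions`
#'   supplied).
#' @param fractions Fractions remaining when `tc` is a plain time vector.
#' @return Object of class `rate_fit`: list with `k` (per minute), `k_se`,
#'   `r_squared`, `n_points`, `converged`, `boundary` (`TRUE` when the fit
#'   sits on the k = 0 bound, e.g. non-decaying data).
#' @export
fit_first_order <- function(tc, fractions = NULL) {
  if (inherits(tc, "timecourse")) {
    t <- tc$times; f <- tc$fractions
  } else {
    t <- as.numeric(tc); f <- as.numeric(fractions)
  }
  stopifnot(length(t) == length(f), length(t) >= 3)
  pos <- f > 0 & t > 0
  k_init <- if (any(pos)) {
    max(0, -sum(t[pos] * log(f[pos])) / sum(t[pos]^2))
  } else 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ exp(-k * t), start = list(k = k_init),
                      lower = c(k = 0),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-14, ptol = 1e-14, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(k = k_init, k_se = NA_real_, r_squared = NA_real_,
                          n_points = length(t), converged = FALSE,
                          boundary = FALSE),
                     class = "rate_fit"))
  }
  k <- unname(coef(fit)["k"])
  k_se <- tryCatch(unname(summary(fit)$coefficients["k", "Std. Error"]),
                   error = function(e) NA_real_)
  resid <- f - exp(-k * t)
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1
  structure(list(k = k, k_se = k_se, r_squared = min(r2, 1),
                 n_points = length(t), converged = TRUE,
                 boundary = k <= .Machine$double.eps^0.5),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> k = %.5g /min (SE %.3g), R^2 = %.4f, n = %d%s\n",
              x$k, x$k_se, x$r_squared, x$n_points,
              if (x$boundary) " [k = 0 boundary]" else ""))
  invisible(x)
}

# rate decay model: k_i = k0 / (1 + ratio / phi)
effectiveness_model <- function(ratio, k0, phi) k0 / (1 + ratio / phi)

# core effectiveness fitter; `require_control` enforces a ratio-0 point
fit_effectiveness_core <- function(ratios, k, fix_k0 = NULL,
                                   require_control = TRUE) {
  ratios <- as.numeric(ratios); k <- as.numeric(k)
  stopifnot(length(ratios) == length(k))
  n_free <- if (is.null(fix_k0)) 2L else 1L
  n_distinct <- length(unique(ratios))
  if (n_distinct < max(2L, n_free + 1L) || length(ratios) <= n_free)
    stop("fit_effectiveness: need more distinct ratios than free parameters")
  if (require_control && is.null(fix_k0) && !any(ratios == 0))
    stop("fit_effectiveness: a ratio-0 (uninhibited) condition is required unless fix_k0 is given")
  if (diff(range(k)) <= 1e-12 * max(abs(k), 1)) {
    k0 <- if (is.null(fix_k0)) mean(k) else fix_k0
    return(list(k0 = k0, phi = Inf, k0_se = NA_real_, phi_se = NA_real_,
                converged = TRUE, no_inhibition = TRUE))
  }
  k0_init <- if (!is.null(fix_k0)) fix_k0
             else if (any(ratios == 0)) mean(k[ratios == 0]) else max(k)
  # per-point inversion of the model: phi_j = ratio_j / (k0/k_j - 1)
  sel <- ratios > 0 & k > 0 & k < k0_init
  phi_init <- if (any(sel)) stats::median(ratios[sel] / (k0_init / k[sel] - 1))
              else stats::median(ratios[ratios > 0])
  if (!is.finite(phi_init) || phi_init <= 0) phi_init <- stats::median(ratios[ratios > 0])
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14, maxiter = 500)
  # direct residual interface (nls.lm): same Levenberg-Marquardt fit as the
  # formula front end, without per-call model-frame overhead
  resid_fn <- if (is.null(fix_k0)) {
    function(p) k - p[1] / (1 + ratios / p[2])
  } else {
    function(p) k - fix_k0 / (1 + ratios / p[1])
  }
  start <- if (is.null(fix_k0)) c(k0 = k0_init, phi = phi_init) else c(phi = phi_init)
  lower <- if (is.null(fix_k0)) c(0, 1e-12) else 1e-12
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower, control = ctrl),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% c(1:4)) {
    return(list(k0 = k0_init, phi = phi_init, k0_se = NA_real_,
                phi_se = NA_real_, converged = FALSE, no_inhibition = FALSE))
  }
  cf <- fit$par
  se <- tryCatch({
    sigma2 <- fit$deviance / max(length(k) - length(cf), 1)
    sqrt(diag(sigma2 * solve(fit$hessian)))
  }, error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  list(k0 = if (is.null(fix_k0)) unname(cf["k0"]) else fix_k0,
       phi = unname(cf["phi"]),
       k0_se = if (is.null(fix_k0)) unname(se["k0"]) else NA_real_,
       phi_se = unname(se["phi"]),
       converged = TRUE, no_inhibition = FALSE)
}

#' Fit the inhibitor effectiveness model
#'
#' Fits k_i = k0 / (1 + r / phi) to per-condition first-order rate
#' constants k_i observed at inhibitor:protein molar ratios r. `phi` (the
#' effectiveness) is the molar ratio at which the cleavage rate constant
#' is halved: the fitted curve passes through k0 / 2 at r = phi. With
#' `fix_k0`, the uninhibited rate constant is held fixed and only phi is
#' estimated. When an initial protein concentration `lexa0` (micromolar)
#' is supplied, the dissociation constant `kd = phi * lexa0` is attached.
#'
#' @param ratios Inhibitor:protein molar ratios (a ratio-0 control is
#'   required unless `fix_k0` is given). May also be a data.frame with
#'   columns `ratio` and `k`, or a list of `(ratio, rate_fit)` pairs from
#'   [fit_timecourses()].
#' @param k Per-condition rate constants (per minute).
#' @param fix_k0 Optional fixed uninhibited rate constant.
#' @param lexa0 Optional protein concentration (micromolar) for the
#'   phi -> Kd conversion.
#' @return Object of class `effectiveness_fit`: `k0`, `phi`, `k0_se`,
#'   `phi_se`, `kd` (micromolar or `NA`), `lexa0_used`, `converged`,
#'   `no_inhibition` (all k_i equal: phi is reported as `Inf`),
#'   `points` (the input table).
#' @export
fit_effectiveness <- function(ratios, k = NULL, fix_k0 = NULL, lexa0 = NULL) {
  if (is.data.frame(ratios)) {
    stopifnot(all(c("ratio", "k") %in% names(ratios)))
    k <- ratios$k; ratios <- ratios$ratio
  }
  res <- fit_effectiveness_core(ratios, k, fix_k0 = fix_k0,
                                require_control = TRUE)
  kd <- if (!is.null(lexa0) && is.finite(res$phi)) kd_from_phi(res$phi, lexa0)
        else NA_real_
  structure(c(res, list(kd = kd,
                        lexa0_used = if (is.null(lexa0)) NA_real_ else lexa0,
                        points = data.frame(ratio = as.numeric(ratios),
                                            k = as.numeric(k)))),
            class = "effectiveness_fit")
}

#' @export
print.effectiveness_fit <- function(x, ...) {
  cat(sprintf("<effectiveness_fit> k0 = %.5g /min, phi = %.4g%s\n",
              x$k0, x$phi,
              if (!is.na(x$kd)) sprintf(", Kd = %.4g uM", x$kd) else ""))
  if (x$no_inhibition) cat("  no inhibition signal (all rate constants equal)\n")
  invisible(x)
}

#' Convert effectiveness to a dissociation constant
#'
#' The effectiveness phi is the inhibitor:protein molar ratio halving the
#' cleavage rate; multiplying by the protein concentration expresses it as
#' the inhibitor concentration doing so, i.e. the dissociation constant of
#' the inhibitor-protein complex under the 1:1 binding assumption.
#'
#' @param phi Effectiveness (dimensionless), positive.
#' @param lexa0 Initial protein concentration, micromolar, positive.
#' @return Kd in micromolar: `phi * lexa0`.
#' @examples
#' kd_from_phi(43.422, molar_concentration(15, 100, LEXA_MW))
#' @export
kd_from_phi <- function(phi, lexa0) {
  if (!is.numeric(phi) || !is.numeric(lexa0) || any(phi <= 0) || any(lexa0 <= 0))
    stop("kd_from_phi: phi and lexa0 must be positive")
  phi * lexa0
}

#' Molar concentration from mass, volume and molecular weight
#'
#' @param mass_ug Mass in micrograms, positive.
#' @param volume_ul Volume in microliters, positive.
#' @param mw Molecular weight in daltons, positive (default [LEXA_MW]).
#' @return Concentration in micromolar.
#' @examples
#' molar_concentration(15, 100, 22358) # ~6.709 uM
#' @export
molar_concentration <- function(mass_ug, volume_ul, mw = LEXA_MW) {
  if (any(c(mass_ug, volume_ul, mw) <= 0))
    stop("molar_concentration: all inputs must be positive")
  (mass_ug / volume_ul) / mw * 1e6
}

#' Bootstrap confidence intervals for the effectiveness fit
#'
#' Case-resampling bootstrap over the (ratio, k) pairs: each replicate
#' resamples the conditions with replacement and refits the effectiveness
#' model. Resamples with too few distinct ratios to identify the free
#' parameters (or failing to converge) are skipped and counted. Intervals
#' are 95 percent percentile intervals; results are deterministic for a
#' fixed seed.
#'
#' @inheritParams fit_effectiveness
#' @param n_boot Number of bootstrap replicates, at least 100.
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @return List with `ci` (matrix: rows k0, phi and, when `lexa0` given,
#'   kd; columns lower, upper), `estimates` (the full-data fit),
#'   `n_boot`, `n_skipped`, `replicates` (data.frame of k0, phi draws).
#' @export
bootstrap_effectiveness <- function(ratios, k = NULL, n_boot = 1000,
                                    seed = 1, fix_k0 = NULL, lexa0 = NULL,
                                    level = 0.95) {
  if (is.data.frame(ratios)) {
    stopifnot(all(c("ratio", "k") %in% names(ratios)))
    k <- ratios$k; ratios <- ratios$ratio
  }
  stopifnot(n_boot >= 100)
  est <- fit_effectiveness(ratios, k, fix_k0 = fix_k0, lexa0 = lexa0)
  n <- length(ratios)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  draws_k0 <- draws_phi <- rep(NA_real_, n_boot)
  n_skipped <- 0L
  n_free <- if (is.null(fix_k0)) 2L else 1L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    r_b <- ratios[idx]; k_b <- k[idx]
    if (length(unique(r_b)) < n_free + 1L) { n_skipped <- n_skipped + 1L; next }
    res <- tryCatch(
      fit_effectiveness_core(r_b, k_b, fix_k0 = fix_k0, require_control = FALSE),
      error = function(e) NULL)
    if (is.null(res) || !res$converged || !is.finite(res$phi)) {
      n_skipped <- n_skipped + 1L; next
    }
    draws_k0[b] <- res$k0; draws_phi[b] <- res$phi
  }
  ok <- is.finite(draws_phi)
  alpha <- (1 - level) / 2
  qs <- function(x) unname(stats::quantile(x[ok], c(alpha, 1 - alpha), type = 7))
  ci <- rbind(k0 = qs(draws_k0), phi = qs(draws_phi))
  if (!is.null(lexa0)) ci <- rbind(ci, kd = qs(draws_phi * lexa0))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimates = est, n_boot = n_boot, n_skipped = n_skipped,
       replicates = data.frame(k0 = draws_k0, phi = draws_phi)[ok, ])
}

#' Fit rate constants for a set of time courses
#'
#' Convenience wrapper: applies [fit_first_order()] to each condition and
#' assembles the (ratio, k) table that [fit_effectiveness()] consumes.
#'
#' @param tcs List of `timecourse` objects (with known ratios).
#' @return data.frame with columns `label`, `ratio`, `inhibitor_conc`, `k`,
#'   `k_se`, `r_squared`, `converged`.
#' @export
fit_timecourses <- function(tcs) {
  stopifnot(length(tcs) >= 1, all(vapply(tcs, inherits, logical(1), "timecourse")))
  rows <- lapply(tcs, function(tc) {
    rf <- fit_first_order(tc)
    data.frame(label = tc$label, ratio = tc$ratio,
               inhibitor_conc = tc$inhibitor_conc, k = rf$k, k_se = rf$k_se,
               r_squared = rf$r_squared, converged = rf$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
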