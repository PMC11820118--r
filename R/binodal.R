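# Coexisting-density extraction from slab density profiles and critical
# point estimation. A slab (direct-coexistence) profile shows a dense
# plateau flanked by dilute plateaus; the two plateau densities at each
# temperature trace the binodal, whose apex (Tc, rho_c) is located by
# fitting the law of coexisting densities (empirical 3.06 exponent from
# the 3D Ising universality class) together with the law of rectilinear
# diameters.

# Exponent of the coexistence law (rho_high - rho_low)^3.06 = d (1 - T/Tc);
# dimensionless empirical factor, fixed, never fitted.
COEX_EXPONENT <- 3.06

#' Construct a density profile
#'
#' @param z ordered bin centres along the long box axis (Angstrom).
#' @param rho mass density per bin (g/cm^3), non-negative.
#' @param err optional per-bin standard error.
#' @return object of class `density_profile`.
#' @export
density_profile <- function(z, rho, err = NULL) {
  stopifnot(length(z) == length(rho), all(diff(z) > 0), all(rho >= 0))
  structure(list(z = as.numeric(z), rho = as.numeric(rho),
                 err = if (is.null(err)) NULL else as.numeric(err)),
            class = "density_profile")
}

#' Read a density profile from CSV
#'
#' Columns: `z_A`, `rho_g_cm3`, optional `err`.
#' @param path CSV path.
#' @return a [density_profile()].
#' @export
read_profile <- function(path) {
  tab <- utils::read.csv(path)
  density_profile(tab$z_A, tab$rho_g_cm3,
                  if ("err" %in% names(tab)) tab$err else NULL)
}

# Re-centre a periodic profile so the dense slab is contiguous: circular
# shift putting the density-weighted circular mean of z at box centre.
recenter_profile <- function(profile) {
  n <- length(profile$z)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  w <- profile$rho / sum(profile$rho)
  mean_theta <- atan2(sum(w * sin(theta)), sum(w * cos(theta))) %% (2 * pi)
  centre_bin <- 1 + round(mean_theta / (2 * pi) * n)
  shift <- (round(n / 2) - centre_bin) %% n
  idx <- ((seq_len(n) - 1 - shift) %% n) + 1
  density_profile(profile$z, profile$rho[idx],
                  if (is.null(profile$err)) NULL else profile$err[idx])
}

#' Extract coexisting densities from a slab density profile
#'
#' Fits the symmetric double-hyperbolic-tangent slab model
#' `rho(z) = rho_low + (rho_high - rho_low)/2 *
#'   (tanh((z - z1)/w) - tanh((z - z2)/w))`
#' by least squares (Levenberg-Marquardt). Initial guesses come from the
#' 10th/90th density percentiles and the half-maximum crossings. The
#' profile is first re-centred so the dense slab does not wrap the
#' periodic boundary. Coexistence is flagged absent when the fitted
#' plateaus differ by less than three times their joint standard error.
#'
#' @param profile a [density_profile()] with at least 20 bins.
#' @return list with `rho_low`, `rho_high`, `err_low`, `err_high`,
#'   `coexistence` (logical), interface positions `z1`, `z2`, width `w`,
#'   and the fit object.
#' @export
extract_coexisting_densities <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  if (length(profile$z) < 20) {
    stop("need at least 20 bins to resolve plateaus and interfaces",
         call. = FALSE)
  }
  pr <- recenter_profile(profile)
  z <- pr$z; rho <- pr$rho
  lo0 <- as.numeric(stats::quantile(rho, 0.10))
  hi0 <- as.numeric(stats::quantile(rho, 0.90))
  # essentially flat profile: single phase, nothing to fit
  if (hi0 - lo0 <= sqrt(.Machine$double.eps) * max(hi0, 1)) {
    m <- mean(rho)
    s <- stats::sd(rho) / sqrt(length(rho))
    return(list(rho_low = m, rho_high = m, err_low = s, err_high = s,
                coexistence = FALSE, z1 = NA_real_, z2 = NA_real_,
                w = NA_real_, fit = NULL))
  }
  half <- (lo0 + hi0) / 2
  above <- rho > half
  if (any(above) && any(!above)) {
    z1_0 <- z[which(above)[1]]
    z2_0 <- z[rev(which(above))[1]]
  } else {
    z1_0 <- as.numeric(stats::quantile(z, 0.35))
    z2_0 <- as.numeric(stats::quantile(z, 0.65))
  }
  w0 <- max(diff(range(z)) / 50, mean(diff(z)))
  dat <- data.frame(z = z, rho = rho)
  args <- list(
    rho ~ rho_low + (rho_high - rho_low) / 2 *
      (tanh((z - z1) / w) - tanh((z - z2) / w)),
    data = dat,
    start = list(rho_low = lo0, rho_high = hi0, z1 = z1_0, z2 = z2_0,
                 w = w0),
    lower = c(0, 0, min(z), min(z), mean(diff(z)) / 100),
    upper = c(Inf, Inf, max(z), max(z), diff(range(z))),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(pr$err) && all(pr$err > 0)) args$weights <- 1 / pr$err^2
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) {
      stop(sprintf(paste0(
        "slab fit did not converge (%s); initial guesses were rho_low=%.4g,",
        " rho_high=%.4g, z1=%.4g, z2=%.4g, w=%.4g"),
        conditionMessage(e), lo0, hi0, z1_0, z2_0, w0), call. = FALSE)
    })
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  rho_low <- unname(cf["rho_low"]); rho_high <- unname(cf["rho_high"])
  err_low <- unname(se["rho_low"]); err_high <- unname(se["rho_high"])
  joint <- sqrt(err_low^2 + err_high^2)
  list(rho_low = rho_low, rho_high = rho_high,
       err_low = err_low, err_high = err_high,
       coexistence = (rho_high - rho_low) > 3 * joint,
       z1 = unname(cf["z1"]), z2 = unname(cf["z2"]), w = unname(cf["w"]),
       fit = fit)
}

#' Assemble a coexistence-point table
#'
#' @param T_K temperatures (Kelvin).
#' @param rho_low,rho_high coexisting densities (g/cm^3).
#' @param err_low,err_high optional standard errors.
#' @return data.frame of class `coexistence_points`.
#' @export
coexistence_points <- function(T_K, rho_low, rho_high,
                               err_low = NA_real_, err_high = NA_real_) {
  stopifnot(all(rho_high > rho_low), all(rho_low > 0))
  out <- data.frame(T_K = T_K, rho_low = rho_low, rho_high = rho_high,
                    err_low = err_low, err_high = err_high)
  class(out) <- c("coexistence_points", "data.frame")
  out
}

#' Fit the critical point of a binodal
#'
#' Simultaneous weighted nonlinear least squares of the coexistence law
#' `(rho_high - rho_low)^3.06 = d (1 - T/Tc)` and the rectilinear-diameter
#' law `(rho_high + rho_low)/2 = rho_c + A (T - Tc)`, parameterised through
#' the branch densities
#' `rho_+/-(T) = rho_c + A (T - Tc) +/- (d (1 - T/Tc))^(1/3.06) / 2`.
#' Per-point errors, when present, enter as inverse-variance weights. The
#' 3.06 exponent is a fixed constant, not a free parameter.
#'
#' @param points a [coexistence_points()] table with at least 3 rows.
#' @return object of class `critical_point`: list with `Tc`, `Tc_err`,
#'   `rho_c`, `d`, `A`, the 4x4 parameter covariance, and the fit object.
#' @export
fit_critical_point <- function(points) {
  stopifnot(inherits(points, "data.frame"))
  if (nrow(points) < 3) {
    stop("need at least 3 coexistence points to fit (Tc, rho_c, d, A)",
         call. = FALSE)
  }
  T_K <- points$T_K
  diff306 <- (points$rho_high - points$rho_low)^COEX_EXPONENT
  # linear pre-fit of the coexistence law gives Tc, d starting values
  lf <- stats::lm(diff306 ~ T_K)
  Tc0 <- -stats::coef(lf)[1] / stats::coef(lf)[2]
  if (!is.finite(Tc0) || Tc0 <= max(T_K)) Tc0 <- max(T_K) + 0.1 * diff(range(T_K))
  d0 <- max(stats::coef(lf)[1], 1e-6)
  mid <- (points$rho_high + points$rho_low) / 2
  lm2 <- stats::lm(mid ~ T_K)
  A0 <- stats::coef(lm2)[2]
  rho_c0 <- stats::coef(lm2)[1] + A0 * Tc0
  dat <- data.frame(
    T_K = rep(T_K, 2),
    rho = c(points$rho_high, points$rho_low),
    sgn = rep(c(1, -1), each = nrow(points)))
  have_err <- all(c("err_low", "err_high") %in% names(points)) &&
    all(is.finite(c(points$err_high, points$err_low))) &&
    all(c(points$err_high, points$err_low) > 0)
  args <- list(
    rho ~ rho_c + A * (T_K - Tc) +
      sgn * 0.5 * (d * pmax(1 - T_K / Tc, 0))^(1 / COEX_EXPONENT),
    data = dat,
    start = list(Tc = unname(Tc0), rho_c = unname(rho_c0),
                 d = unname(d0), A = unname(A0)),
    lower = c(max(T_K), -Inf, 1e-12, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000))
  if (have_err) args$weights <- 1 / c(points$err_high, points$err_low)^2
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) {
      stop("critical-point fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) {
    warning("ill-conditioned critical-point fit; covariance unavailable (",
            conditionMessage(e), ")")
    matrix(NA_real_, 4, 4)
  })
  kappa_cond <- tryCatch(kappa(vc), error = function(e) NA_real_)
  if (is.finite(kappa_cond) && kappa_cond > 1e12) {
    warning("ill-conditioned critical-point fit (covariance condition ",
            format(kappa_cond, digits = 3), ")")
  }
  if (unname(cf["Tc"]) <= max(T_K)) {
    stop("fitted Tc (", round(unname(cf["Tc"]), 2),
         " K) does not exceed the highest fitted temperature; points above",
         " the apparent critical temperature?", call. = FALSE)
  }
  structure(list(Tc = unname(cf["Tc"]),
                 Tc_err = sqrt(vc["Tc", "Tc"]),
                 rho_c = unname(cf["rho_c"]),
                 d = unname(cf["d"]), A = unname(cf["A"]),
                 covariance = vc, fit = fit),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("<critical_point> Tc = %.2f +/- %.2f K, rho_c = %.4f g/cm^3\n",
              x$Tc, x$Tc_err, x$rho_c))
  cat(sprintf("  d = %.4g, A = %.4g\n", x$d, x$A))
  invisible(x)
}

#' Closed-form binodal from a critical point
#'
#' Inverts the coexistence and rectilinear-diameter laws:
#' `rho_+/-(T) = rho_c + A (T - Tc) +/- (d (1 - T/Tc))^(1/3.06) / 2`.
#'
#' @param cp a `critical_point` (or list with `Tc`, `rho_c`, `d`, `A`).
#' @param temps temperatures (Kelvin), all strictly below `Tc`.
#' @return a [coexistence_points()] table.
#' @export
predict_binodal <- function(cp, temps) {
  if (any(temps >= cp$Tc)) {
    stop("all temperatures must lie below Tc = ", round(cp$Tc, 2), " K",
         call. = FALSE)
  }
  half <- 0.5 * (cp$d * (1 - temps / cp$Tc))^(1 / COEX_EXPONENT)
  mid <- cp$rho_c + cp$A * (temps - cp$Tc)
  coexistence_points(temps, mid - half, mid + half)
}

#' Critical-temperature difference between two fitted systems
#'
#' `delta Tc = Tc(variant) - Tc(reference)`, with the uncertainty from
#' standard error propagation, `sqrt(err_var^2 + err_ref^2)`.
#'
#' @param variant,wt `critical_point` objects (or lists with `Tc`,
#'   `Tc_err`).
#' @return list with `value` and `error` (Kelvin).
#' @export
delta_tc <- function(variant, wt) {
  list(value = variant$Tc - wt$Tc,
       error = sqrt(variant$Tc_err^2 + wt$Tc_err^2))
}

#' Serialise a critical-point fit to JSON
#' @param cp a `critical_point`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_critical_point <- function(cp, path) {
  jsonlite::write_json(
    list(Tc = cp$Tc, Tc_err = cp$Tc_err, rho_c = cp$rho_c, d = cp$d,
         A = cp$A, covariance = cp$covariance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
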