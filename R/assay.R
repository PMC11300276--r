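# Quantitative assay analyses: CD melt curves (two-state fit, fraction
# folded, reversibility), ELISA binding curves (4PL), positivity ratios and
# wound-healing rates.

#' Mean-residue molar ellipticity
#'
#' Converts raw ellipticity (mdeg) to mean-residue molar ellipticity
#' (deg cm^2 dmol^-1): `theta / (10 * pathlength_cm * concentration_M *
#' n_residues)`.
#'
#' @param raw_mdeg raw ellipticity in millidegrees.
#' @param pathlength_cm cuvette pathlength (cm).
#' @param concentration_M protein concentration (mol/L).
#' @param n_residues residues per protein chain.
#' @return mean-residue molar ellipticity, with attribute
#'   `convention = "mean-residue"`.
#' @export
molar_ellipticity <- function(raw_mdeg, pathlength_cm, concentration_M,
                              n_residues) {
  if (pathlength_cm <= 0 || concentration_M <= 0 || n_residues <= 0) {
    stop("pathlength, concentration and residue count must be positive",
         call. = FALSE)
  }
  out <- raw_mdeg / (10 * pathlength_cm * concentration_M * n_residues)
  attr(out, "convention") <- "mean-residue"
  out
}

#' Fraction folded from a melt signal and baselines
#'
#' `f(T) = (theta(T) - theta_U(T)) / (theta_F(T) - theta_U(T))` with linear
#' folded/unfolded baselines, clipped to `[0, 1]` (clipping flagged).
#'
#' @param temperature temperatures (deg C).
#' @param signal ellipticity at each temperature.
#' @param folded_baseline,unfolded_baseline numeric `c(intercept, slope)`.
#' @return list: `fraction` (per temperature), `clipped` (logical vector).
#' @export
fraction_folded <- function(temperature, signal, folded_baseline,
                            unfolded_baseline) {
  th_f <- folded_baseline[1L] + folded_baseline[2L] * temperature
  th_u <- unfolded_baseline[1L] + unfolded_baseline[2L] * temperature
  if (any(abs(th_f - th_u) < .Machine$double.eps^0.5)) {
    stop("degenerate baselines: folded and unfolded signals coincide",
         call. = FALSE)
  }
  f <- (signal - th_u) / (th_f - th_u)
  clipped <- f < 0 | f > 1
  list(fraction = pmin(pmax(f, 0), 1), clipped = clipped)
}

.check_melt_curve <- function(temperature, signal) {
  if (length(temperature) != length(signal)) {
    stop("temperature and signal lengths differ", call. = FALSE)
  }
  if (length(temperature) < 8L) {
    stop("melt curve needs at least 8 points", call. = FALSE)
  }
  if (any(diff(temperature) <= 0)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
}

#' Fit a two-state thermal melt
#'
#' Nonlinear least squares of a two-state sigmoid with linear pre- and
#' post-transition baselines:
#' `theta(T) = (aF + bF T) f(T) + (aU + bU T) (1 - f(T))` with
#' `f(T) = 1 / (1 + exp((T - Tm) / w))`. Initialization is deterministic:
#' `Tm0` is the temperature of steepest numerical gradient, baselines come
#' from the outer quartiles of the temperature range. A van't Hoff enthalpy
#' (`dH = R Tm^2 / w`, kJ/mol, Tm in kelvin) is emitted for convenience but
#' is not part of the fit contract.
#'
#' @param temperature temperatures (deg C), strictly increasing.
#' @param signal ellipticity at each temperature.
#' @param min_snr minimum ratio of signal change to point-to-point noise for
#'   a transition to be declared.
#' @return object of class `melt_fit`: `tm`, `width`, `folded_baseline`,
#'   `unfolded_baseline` (intercept/slope pairs), `fraction_folded`,
#'   `fitted`, `residual_sd`, `dH_vanthoff`.
#' @export
fit_two_state_melt <- function(temperature, signal, min_snr = 5) {
  .check_melt_curve(temperature, signal)
  n <- length(temperature)
  noise <- stats::mad(diff(signal)) / sqrt(2)
  amplitude <- abs(diff(range(signal)))
  if (amplitude < min_snr * max(noise, .Machine$double.eps)) {
    stop("no transition detected: signal change below noise floor",
         call. = FALSE)
  }
  # deterministic initialization
  grad <- abs(diff(signal) / diff(temperature))
  tm0 <- temperature[which.max(grad)]
  lo <- temperature <= stats::quantile(temperature, 0.25)
  hi <- temperature >= stats::quantile(temperature, 0.75)
  cf <- stats::coef(stats::lm(signal[lo] ~ temperature[lo]))
  cu <- stats::coef(stats::lm(signal[hi] ~ temperature[hi]))
  start <- list(aF = unname(cf[1L]), bF = unname(cf[2L]),
                aU = unname(cu[1L]), bU = unname(cu[2L]),
                tm = tm0, w = diff(range(temperature)) / 30)
  df <- data.frame(x = temperature, y = signal)
  fit <- try(suppressWarnings(stats::nls(
    y ~ (aF + bF * x) / (1 + exp((x - tm) / w)) +
      (aU + bU * x) * (1 - 1 / (1 + exp((x - tm) / w))),
    data = df, start = start, algorithm = "port",
    lower = c(aF = -Inf, bF = -Inf, aU = -Inf, bU = -Inf,
              tm = min(temperature), w = 0.05),
    upper = c(aF = Inf, bF = Inf, aU = Inf, bU = Inf,
              tm = max(temperature), w = diff(range(temperature))),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # fall back to direct RSS minimization from the same start
    obj <- function(p) {
      f <- 1 / (1 + exp((temperature - p[5L]) / max(p[6L], 0.05)))
      sum((signal - ((p[1L] + p[2L] * temperature) * f +
                       (p[3L] + p[4L] * temperature) * (1 - f)))^2)
    }
    op <- stats::optim(unlist(start), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    p <- op$par
    names(p) <- names(start)
  } else {
    p <- stats::coef(fit)
  }
  f <- 1 / (1 + exp((temperature - p[["tm"]]) / p[["w"]]))
  fitted <- (p[["aF"]] + p[["bF"]] * temperature) * f +
    (p[["aU"]] + p[["bU"]] * temperature) * (1 - f)
  frac <- fraction_folded(temperature, signal,
                          c(p[["aF"]], p[["bF"]]), c(p[["aU"]], p[["bU"]]))
  tm_k <- p[["tm"]] + 273.15
  structure(list(
    tm = unname(p[["tm"]]), width = unname(p[["w"]]),
    folded_baseline = c(intercept = unname(p[["aF"]]), slope = unname(p[["bF"]])),
    unfolded_baseline = c(intercept = unname(p[["aU"]]), slope = unname(p[["bU"]])),
    fraction_folded = frac$fraction, clipped = frac$clipped,
    fitted = fitted, residual_sd = stats::sd(signal - fitted),
    dH_vanthoff = 8.314462618e-3 * tm_k^2 / unname(p[["w"]])
  ), class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> Tm = %.2f degC (width %.2f, residual sd %.3g)\n",
              x$tm, x$width, x$residual_sd))
  invisible(x)
}

#' Thermal reversibility
#'
#' Percent of the folded signal amplitude recovered after cooling a melted
#' sample back to the pre-melt temperature:
#' `100 * (post - baseline) / (pre - baseline)`. Inputs may be vectors of
#' replicate readings (averaged).
#'
#' @param pre_signal folded signal before melting (e.g. at 25 deg C).
#' @param post_signal signal after melt-and-cool at the same temperature.
#' @param baseline unfolded-state reference signal used for amplitude
#'   correction (default 0).
#' @return reversibility percentage.
#' @export
reversibility <- function(pre_signal, post_signal, baseline = 0) {
  pre_amp <- mean(pre_signal) - mean(baseline)
  post_amp <- mean(post_signal) - mean(baseline)
  if (abs(pre_amp) < .Machine$double.eps^0.5) {
    stop("zero pre-melt amplitude", call. = FALSE)
  }
  100 * post_amp / pre_amp
}

#' Fit a four-parameter logistic binding curve
#'
#' `y = bottom + (top - bottom) / (1 + (ec50 / x)^hill)`, with the fitted
#' EC50 reported as the apparent KD of an indirect ELISA titration. A seeded
#' residual bootstrap provides a percentile confidence interval. The fit is
#' flagged unreliable when the response is flat, when the series does not
#' approach saturation, or when the EC50 falls outside the concentration
#' range.
#'
#' @param concentration ligand concentrations (molar), positive and distinct.
#' @param response assay response (e.g. A450).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return object of class `binding_fit`: `ec50` (apparent KD, molar),
#'   `hill`, `top`, `bottom`, `ci` (bootstrap percentile interval),
#'   `reliable`, `flags`, `fitted`.
#' @export
fit_binding_curve <- function(concentration, response, n_boot = 199L,
                              seed = 1L, conf = 0.95) {
  if (length(concentration) < 6L) {
    stop("need at least 6 concentrations", call. = FALSE)
  }
  if (any(concentration <= 0) || anyDuplicated(concentration)) {
    stop("concentrations must be positive and distinct", call. = FALSE)
  }
  if (length(response) != length(concentration)) {
    stop("concentration and response lengths differ", call. = FALSE)
  }
  ord <- order(concentration)
  x <- concentration[ord]; y <- response[ord]
  flags <- character(0)
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (diff(range(y)) < max(6 * noise, .Machine$double.eps)) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, ci = c(NA_real_, NA_real_),
                          reliable = FALSE, flags = "constant_response",
                          fitted = rep(mean(y), length(y))),
                     class = "binding_fit"))
  }
  fit4pl <- function(x, y) {
    b0 <- min(y); t0 <- max(y)
    half <- b0 + (t0 - b0) / 2
    e0 <- x[which.min(abs(y - half))]
    suppressWarnings(stats::nls(y ~ bottom + (top - bottom) / (1 + (ec50 / x)^hill),
               data = data.frame(x = x, y = y),
               start = list(bottom = b0, top = t0, ec50 = e0, hill = 1),
               algorithm = "port",
               lower = c(bottom = -Inf, top = -Inf, ec50 = min(x) / 100,
                         hill = 0.1),
               upper = c(bottom = Inf, top = Inf, ec50 = max(x) * 100,
                         hill = 10),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)))
  }
  fit <- fit4pl(x, y)
  p <- stats::coef(fit)
  fitted <- p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + (p[["ec50"]] / x)^p[["hill"]])
  if (p[["ec50"]] < min(x) || p[["ec50"]] > max(x)) {
    flags <- c(flags, "ec50_outside_range")
  }
  # saturation: the top observed response should reach 90% of the fitted top
  if (max(y) < p[["bottom"]] + 0.9 * (p[["top"]] - p[["bottom"]])) {
    flags <- c(flags, "non_saturating")
  }
  resid <- y - fitted
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      yb <- fitted + sample(resid, length(resid), replace = TRUE)
      fb <- try(fit4pl(x, yb), silent = TRUE)
      if (inherits(fb, "try-error")) NA_real_ else stats::coef(fb)[["ec50"]]
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  alpha <- (1 - conf) / 2
  ci <- if (length(boot) >= 20L) {
    unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(ec50 = unname(p[["ec50"]]), hill = unname(p[["hill"]]),
                 top = unname(p[["top"]]), bottom = unname(p[["bottom"]]),
                 ci = ci, reliable = length(flags) == 0L, flags = flags,
                 fitted = fitted),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (is.na(x$ec50)) {
    cat("<binding_fit> unreliable:", paste(x$flags, collapse = ", "), "\n")
  } else {
    cat(sprintf("<binding_fit> EC50 (apparent KD) = %.3g M [%.3g, %.3g], hill %.2f%s\n",
                x$ec50, x$ci[1L], x$ci[2L], x$hill,
                if (!x$reliable) paste0(" (flags: ",
                                        paste(x$flags, collapse = ", "), ")")
                else ""))
  }
  invisible(x)
}

#' Absorbance (or fluorescence) ratio with positivity call
#'
#' Ratio of the experimental to the control reading; positive when the ratio
#' strictly exceeds the threshold (default 2, the phage-ELISA rule).
#'
#' @param experimental experimental-group reading (e.g. A450).
#' @param control control-group reading; must be positive.
#' @param positivity_threshold strict positivity threshold.
#' @return list: `ratio`, `positive`.
#' @export
absorbance_ratio <- function(experimental, control, positivity_threshold = 2) {
  if (any(control <= 0)) stop("control reading must be positive", call. = FALSE)
  ratio <- experimental / control
  list(ratio = ratio, positive = ratio > positivity_threshold)
}

#' Wound-healing (scratch closure) rate
#'
#' `rate(t) = (area(0) - area(t)) / area(0) * 100`. Negative values (wound
#' growth) are permitted and flagged.
#'
#' @param areas wound areas, one per timepoint.
#' @param times timepoints in hours; must include 0.
#' @return data frame: `time_h`, `healing_rate_pct`, `negative` flag.
#' @export
wound_healing_rate <- function(areas, times = c(0, 24, 48)) {
  stopifnot(length(areas) == length(times))
  if (!0 %in% times) stop("missing 0 h baseline", call. = FALSE)
  a0 <- areas[match(0, times)]
  if (a0 <= 0) stop("wound area at 0 h must be positive", call. = FALSE)
  rate <- (a0 - areas) / a0 * 100
  data.frame(time_h = times, healing_rate_pct = rate, negative = rate < 0)
}
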