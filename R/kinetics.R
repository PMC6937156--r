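# Michaelis-Menten kinetics: initial-rate fitting, the Lambert-W closed form
# of the integrated rate law, the progress-curve linearization, and the
# competitive-inhibition K_I fit.

#' Molar absorptivity of the peptide bond at 225 nm
#'
#' Default extinction coefficient (376 1/(M cm)) used to convert the
#' absorbance decrease accompanying peptide-bond hydrolysis into a molar
#' rate.
#' @export
EPSILON_225 <- 376

#' Convert an absorbance slope to a molar rate
#'
#' Hydrolysis is followed as a *decrease* in absorbance; the returned rate is
#' positive regardless of the slope's sign.
#'
#' @param dA_dt absorbance change, AU/s.
#' @param epsilon molar absorptivity, 1/(M cm); default [EPSILON_225].
#' @param path_length optical path, cm.
#' @return rate in M/s.
#' @export
absorbance_to_rate <- function(dA_dt, epsilon = EPSILON_225, path_length = 1) {
  if (any(epsilon <= 0)) stop("epsilon must be positive")
  if (any(path_length <= 0)) stop("path_length must be positive")
  abs(dA_dt) / (epsilon * path_length)
}

#' Fit the Michaelis-Menten equation to initial rates
#'
#' Nonlinear least squares of v = Vmax s / (KM + s), started from
#' KM = median(s), Vmax = 1.2 max(v). With `enzyme_conc` given, kcat and
#' kcat/KM are derived.
#'
#' @param substrate_concs substrate concentrations, M (>= 4 distinct values).
#' @param rates initial rates, M/s (non-negative).
#' @param enzyme_conc optional enzyme concentration, M.
#' @return object of class `tsa_mm_fit`: Vmax, KM, their standard errors,
#'   kcat, kcat_over_KM (when enzyme_conc given), `ill_conditioned_km` flag
#'   (TRUE when all substrate concentrations exceed 10 x fitted KM) and the
#'   underlying `nls` fit.
#' @export
fit_michaelis_menten <- function(substrate_concs, rates, enzyme_conc = NULL) {
  s <- as.numeric(substrate_concs); v <- as.numeric(rates)
  if (length(s) != length(v)) stop("substrate and rate vectors differ in length")
  if (length(unique(s)) < 4)
    stop("need >= 4 distinct substrate concentrations, got ", length(unique(s)))
  if (any(v < 0)) stop("negative rates")
  if (any(s <= 0)) stop("non-positive substrate concentrations")
  # fit in scaled units (s/median(s), v/max(v)) so convergence tolerances are
  # meaningful at any absolute data scale; the port algorithm handles the
  # zero-residual (noiseless) case cleanly
  sm <- stats::median(s); vm <- max(v)
  start <- list(Vmax = 1.2, KM = 1)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(vs ~ Vmax * ss / (KM + ss),
                 data = data.frame(ss = s / sm, vs = v / vm), start = start,
                 algorithm = "port", lower = c(1e-10, 1e-10),
                 control = stats::nls.control(maxiter = 500,
                                              warnOnly = TRUE))),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("Michaelis-Menten fit failed to converge: ", conditionMessage(fit),
         " (start Vmax=", signif(1.2 * vm, 3), ", KM=", signif(sm, 3),
         ", n=", length(s), ")")
  converged <- isTRUE(fit$convInfo$isConv)
  # a saturating-only design leaves KM unidentifiable: the solver reports
  # singular convergence; that case is flagged below, not fatal
  saturating <- min(s) > 10 * stats::coef(fit)["KM"] * sm
  if (!converged && !saturating)
    stop("Michaelis-Menten fit failed to converge: ",
         fit$convInfo$stopMessage,
         " (start Vmax=", signif(1.2 * vm, 3), ", KM=", signif(sm, 3),
         ", n=", length(s), ")")
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(co)) { # singular Jacobian: estimates usable, no SEs
    co <- cbind(Estimate = stats::coef(fit),
                `Std. Error` = c(NA_real_, NA_real_))
  }
  co[, 1:2] <- co[, 1:2] * c(vm, sm) # back to M/s and M
  out <- list(Vmax = co["Vmax", "Estimate"], KM = co["KM", "Estimate"],
              Vmax_se = co["Vmax", "Std. Error"], KM_se = co["KM", "Std. Error"],
              enzyme_conc = enzyme_conc, kcat = NULL, kcat_se = NULL,
              kcat_over_KM = NULL, n = length(s), fit = fit,
              ill_conditioned_km = FALSE)
  if (out$Vmax <= 0 || out$KM <= 0)
    stop("Michaelis-Menten fit returned non-positive parameters")
  if (min(s) > 10 * out$KM) {
    out$ill_conditioned_km <- TRUE
    warning("all substrate concentrations exceed 10 x fitted KM; ",
            "KM is ill-conditioned")
  }
  if (!is.null(enzyme_conc)) {
    if (enzyme_conc <= 0) stop("enzyme_conc must be positive")
    out$kcat <- out$Vmax / enzyme_conc
    out$kcat_se <- out$Vmax_se / enzyme_conc
    out$kcat_over_KM <- out$kcat / out$KM
  }
  class(out) <- "tsa_mm_fit"
  out
}

#' @export
print.tsa_mm_fit <- function(x, ...) {
  cat(sprintf("<tsa_mm_fit> Vmax = %.3e +/- %.1e M/s, KM = %.3e +/- %.1e M\n",
              x$Vmax, x$Vmax_se, x$KM, x$KM_se))
  if (!is.null(x$kcat))
    cat(sprintf("  kcat = %.3g 1/s, kcat/KM = %.3g 1/(M s)\n",
                x$kcat, x$kcat_over_KM))
  invisible(x)
}

#' Principal branch of the Lambert W function
#'
#' Solves w exp(w) = exp(log_z) given the *logarithm* of the argument, which
#' keeps the integrated rate law overflow-free when s0/KM' is large. Newton
#' iteration on w + log(w) = log_z for positive arguments; plain Halley
#' iteration otherwise.
#'
#' @param log_z log of the argument (argument must be positive here).
#' @return W0(exp(log_z)), same length as `log_z`.
#' @export
lambert_w0_exp <- function(log_z) {
  w <- ifelse(log_z > 1, log_z - log(pmax(log_z, 1e-300)), exp(pmin(log_z, 1)))
  w <- pmax(w, 1e-300)
  for (i in 1:100) {
    f <- w + log(w) - log_z
    w_new <- pmax(w - f * w / (w + 1), w * 1e-8)
    if (all(abs(w_new - w) <= 1e-15 * pmax(abs(w_new), 1e-300))) {
      w <- w_new; break
    }
    w <- w_new
  }
  w
}

#' Substrate concentration from the integrated Michaelis-Menten law
#'
#' Closed-form solution s(t) of Vmax t = KM' ln(s0/s) + (s0 - s), with
#' KM' = KM_scale x KM (KM_scale = 1 + I/K_I for a competitive inhibitor),
#' via the Lambert W function:
#'   s(t) = KM' W0( (s0/KM') exp((s0 - Vmax t)/KM') ).
#'
#' @param s0 initial substrate concentration, M.
#' @param Vmax maximal rate, M/s.
#' @param KM Michaelis constant, M.
#' @param t time(s), s (non-negative, vectorized).
#' @param KM_scale apparent-KM multiplier, >= 1 for inhibited curves.
#' @return substrate concentration(s), M; s(0) = s0 exactly.
#' @export
closed_form_progress <- function(s0, Vmax, KM, t, KM_scale = 1) {
  if (s0 <= 0 || Vmax <= 0 || KM <= 0 || KM_scale <= 0)
    stop("s0, Vmax, KM, KM_scale must all be positive")
  if (any(t < 0)) stop("t must be non-negative")
  KMp <- KM * KM_scale
  log_z <- log(s0 / KMp) + (s0 - Vmax * t) / KMp
  s <- KMp * lambert_w0_exp(log_z)
  s[t == 0] <- s0
  pmin(s, s0)
}

# summary.lm warns on zero-residual fits; noiseless oracle data hit that
# routinely, so the warning is muffled (and only that one).
.quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Build a progress-curve object
#'
#' @param times observation times, s (strictly increasing, >= 0).
#' @param substrate substrate concentrations, M.
#' @param s0 initial substrate concentration, M (declared, not estimated).
#' @param I inhibitor concentration, M.
#' @param meta optional list of metadata (e.g. simulation truth).
#' @return object of class `tsa_progress_curve`.
#' @export
progress_curve <- function(times, substrate, s0, I = 0, meta = list()) {
  times <- as.numeric(times); substrate <- as.numeric(substrate)
  if (length(times) != length(substrate)) stop("times/substrate length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 0)) stop("negative times")
  if (s0 <= 0) stop("s0 must be positive")
  if (I < 0) stop("negative inhibitor concentration")
  if (any(substrate <= 0)) stop("non-positive substrate values")
  structure(list(times = times, substrate = substrate, s0 = s0, I = I,
                 meta = meta),
            class = "tsa_progress_curve")
}

#' @export
print.tsa_progress_curve <- function(x, ...) {
  cat(sprintf("<tsa_progress_curve> %d points, s0 = %.3e M, I = %.3e M, conversion %.0f%%\n",
              length(x$times), x$s0, x$I,
              100 * (1 - min(x$substrate) / x$s0)))
  invisible(x)
}

#' Linearize a progress curve and extract (KM/Vmax)app
#'
#' Each usable point is mapped to x = (s0 - s)/ln(s0/s), y = t/ln(s0/s); an
#' ordinary least-squares line then gives intercept = (KM/Vmax)app (s) and
#' slope = 1/Vmax (s/M). Points with fractional conversion outside
#' [min_conversion, max_conversion] are excluded: the transform divides by
#' ln(s0/s), which is unstable near t = 0, and late points are dominated by
#' baseline drift.
#'
#' @param curve a `tsa_progress_curve`.
#' @param min_conversion,max_conversion retention window on fractional
#'   conversion (defaults 0.05, 0.95).
#' @return object of class `tsa_linearization`: km_over_vmax (s), inv_vmax
#'   (s/M), their standard errors, r_squared, n_points, I.
#' @export
linearize_and_fit <- function(curve, min_conversion = 0.05,
                              max_conversion = 0.95) {
  s <- curve$substrate; t <- curve$times; s0 <- curve$s0
  conv <- 1 - s / s0
  keep <- conv >= min_conversion & conv <= max_conversion
  s <- s[keep]; t <- t[keep]
  if (length(s) < 5)
    stop("fewer than 5 usable points after the conversion filter (",
         sum(keep), " retained)")
  if (any(s >= s0))
    stop("retained point with s >= s0: ln(s0/s) undefined")
  lns <- log(s0 / s)
  x <- (s0 - s) / lns
  y <- t / lns
  fit <- stats::lm(y ~ x)
  sm <- .quiet_summary(fit)
  co <- sm$coefficients
  km_over_vmax <- co[1, 1]; inv_vmax <- co[2, 1]
  if (km_over_vmax <= 0 || inv_vmax <= 0)
    stop("fit rejected: non-positive intercept (", signif(km_over_vmax, 3),
         ") or slope (", signif(inv_vmax, 3), ")")
  structure(list(km_over_vmax = km_over_vmax, inv_vmax = inv_vmax,
                 km_over_vmax_se = co[1, 2], inv_vmax_se = co[2, 2],
                 r_squared = sm$r.squared,
                 n_points = length(s), I = curve$I),
            class = "tsa_linearization")
}

#' @export
print.tsa_linearization <- function(x, ...) {
  cat(sprintf("<tsa_linearization> (KM/Vmax)app = %.4g s, 1/Vmax = %.4g s/M, n = %d, I = %.3g M\n",
              x$km_over_vmax, x$inv_vmax, x$n_points, x$I))
  invisible(x)
}

#' Competitive-inhibition K_I from apparent KM/Vmax values
#'
#' Ordinary least squares of (KM/Vmax)app on inhibitor concentration:
#' (KM/Vmax)app = (KM/Vmax)0 (1 + I/K_I), so K_I = intercept/slope. The K_I
#' standard error comes from first-order propagation of the line's parameter
#' covariance. A slope that is non-positive within one standard error is
#' reported as "no measurable inhibition" (K_I = NA) rather than a number.
#'
#' @param apparent data.frame with columns `I` (M) and `km_over_vmax` (s), or
#'   a list of `tsa_linearization` objects; >= 3 inhibitor levels including
#'   an uninhibited (I = 0) reference.
#' @return object of class `tsa_inhibition_fit`: K_I (M or NA), K_I_se,
#'   km_over_vmax_0 and its se, `determinable` flag, and the per-level table.
#' @export
fit_inhibition <- function(apparent) {
  if (is.list(apparent) && !is.data.frame(apparent) &&
      all(vapply(apparent, inherits, logical(1), "tsa_linearization"))) {
    apparent <- data.frame(
      I = vapply(apparent, `[[`, numeric(1), "I"),
      km_over_vmax = vapply(apparent, `[[`, numeric(1), "km_over_vmax"))
  }
  I <- apparent$I; app <- apparent$km_over_vmax
  if (length(I) < 3) stop("need >= 3 inhibitor levels, got ", length(I))
  if (min(I) > 0)
    warning("no uninhibited (I = 0) reference among the inhibitor levels")
  fit <- stats::lm(app ~ I)
  sm <- .quiet_summary(fit)
  co <- sm$coefficients
  a <- co[1, 1]; b <- co[2, 1]
  a_se <- co[1, 2]; b_se <- co[2, 2]
  out <- list(K_I = NA_real_, K_I_se = NA_real_, km_over_vmax_0 = a,
              km_over_vmax_0_se = a_se, slope = b, slope_se = b_se,
              determinable = FALSE,
              levels = data.frame(I = I, km_over_vmax = app))
  if (b <= 0 || (b_se > 0 && b <= b_se)) {
    class(out) <- "tsa_inhibition_fit"
    return(out)
  }
  V <- sm$cov.unscaled * sm$sigma^2
  K_I <- a / b
  # delta method on a/b
  var_KI <- V[1, 1] / b^2 + a^2 * V[2, 2] / b^4 - 2 * a * V[1, 2] / b^3
  out$K_I <- K_I
  out$K_I_se <- sqrt(max(var_KI, 0))
  out$determinable <- TRUE
  class(out) <- "tsa_inhibition_fit"
  out
}

#' @export
print.tsa_inhibition_fit <- function(x, ...) {
  if (x$determinable)
    cat(sprintf("<tsa_inhibition_fit> K_I = %.3e +/- %.1e M, (KM/Vmax)0 = %.4g s\n",
                x$K_I, x$K_I_se, x$km_over_vmax_0))
  else
    cat("<tsa_inhibition_fit> no measurable inhibition (slope <= 0 within its SE)\n")
  invisible(x)
}

#' Read and write progress-curve files
#'
#' Delimited text, one curve per file: comment header lines `#s0=`, `#I=`,
#' `#epsilon=`, `#path_cm=` followed by a header row and columns `time_s`
#' plus either `substrate_M` or `absorbance_AU`. An absorbance trace is
#' converted to substrate via s = s0 - (A[1] - A)/(epsilon path).
#'
#' @param path file path.
#' @return a `tsa_progress_curve`.
#' @export
read_progress_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key, default = NA_real_) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    as.numeric(sub(paste0("^#", key, "="), "", m[1]))
  }
  s0 <- getv("s0")
  if (!is.finite(s0)) stop("curve file lacks '#s0=' header: ", path)
  I <- getv("I", 0)
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"time_s" %in% names(tab)) stop("no time_s column in ", path)
  if ("substrate_M" %in% names(tab)) {
    s <- tab$substrate_M
  } else if ("absorbance_AU" %in% names(tab)) {
    eps <- getv("epsilon", EPSILON_225)
    pl <- getv("path_cm", 1)
    A <- tab$absorbance_AU
    s <- s0 - (A[1] - A) / (eps * pl)
  } else stop("no substrate_M or absorbance_AU column in ", path)
  progress_curve(tab$time_s, s, s0 = s0, I = I)
}

#' @rdname read_progress_curve
#' @param curve a `tsa_progress_curve`.
#' @export
write_progress_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#s0=%.10e", curve$s0), sprintf("#I=%.10e", curve$I)),
             con)
  utils::write.table(data.frame(time_s = curve$times,
                                substrate_M = curve$substrate),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Time to reach a given fractional conversion
#'
#' Inverts the integrated rate law (which is explicit in t) for the default
#' simulation time grids.
#'
#' @param s0,Vmax,KM,KM_scale as in [closed_form_progress()].
#' @param conversion fractional conversion in (0, 1).
#' @return time in seconds.
#' @export
time_to_conversion <- function(s0, Vmax, KM, conversion, KM_scale = 1) {
  if (conversion <= 0 || conversion >= 1) stop("conversion must be in (0, 1)")
  s <- s0 * (1 - conversion)
  (KM * KM_scale * log(s0 / s) + (s0 - s)) / Vmax
}
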