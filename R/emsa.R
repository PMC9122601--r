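#' Fractional saturation from band intensities
#'
#' `Y = 1 - I_T / I_C`, where `I_T` is the unbound-band intensity in a
#' test lane and `I_C` the unbound-band intensity in the zero-protein
#' control lane.  Noisy lanes with `I_T > I_C` give `Y < 0`; such values
#' are retained (clipping would bias the downstream fit).
#'
#' @param I_T test-lane intensity (>= 0), vectorized.
#' @param I_C control-lane intensity (> 0), vectorized.
#' @return fractional saturation Y.
#' @examples
#' fractional_saturation(0.25, 1) # 0.75
#' @export
fractional_saturation <- function(I_T, I_C) {
  assert_that(all(I_C > 0), "fractional_saturation: I_C must be > 0")
  1 - I_T / I_C
}

#' Construct a binding curve from titration measurements
#'
#' @param points data frame with columns `conc` (protein concentration,
#'   nM), `I_T`, `I_C` (band intensities, same arbitrary units) and
#'   optionally `replicate`; `Y` is derived per point.
#' @param probe_id probe identifier.
#' @return object of class `binding_curve` (a data frame with derived
#'   `Y`).
#' @export
binding_curve <- function(points, probe_id = "probe") {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  assert_that(all(c("conc", "I_T", "I_C") %in% names(points)),
              "binding_curve: need columns conc, I_T, I_C")
  assert_that(all(points$conc >= 0), "binding_curve: conc must be >= 0")
  if (is.null(points$replicate)) points$replicate <- 1L
  points$Y <- fractional_saturation(points$I_T, points$I_C)
  points$probe_id <- probe_id
  structure(points[, c("probe_id", "conc", "replicate", "I_T", "I_C", "Y")],
            class = c("binding_curve", "data.frame"))
}

#' Per-concentration mean saturation and standard error
#'
#' @param curve a [binding_curve()].
#' @return data frame `conc`, `n`, `mean_Y`, `sem_Y` (sample sd over
#'   sqrt(k); `NA` for a single replicate).
#' @export
saturation_table <- function(curve) {
  sp <- split(curve$Y, curve$conc)
  concs <- as.numeric(names(sp))
  out <- data.frame(
    conc = concs,
    n = vapply(sp, length, 0L),
    mean_Y = vapply(sp, mean, 0),
    sem_Y = vapply(sp, function(y) {
      if (length(y) < 2) NA_real_ else sd(y) / sqrt(length(y))
    }, 0),
    stringsAsFactors = FALSE)
  out <- out[order(out$conc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate a dissociation constant from a saturation curve
#'
#' Least-squares fit of the binding isotherm
#' `Y(c) = ymax * c^n / (Kd^n + c^n)` to the per-point fractional
#' saturations (hyperbolic model: Hill coefficient n fixed at 1; `"hill"`
#' frees n).  Kd is initialized at the concentration where linear
#' interpolation of the per-concentration mean Y crosses half of max(Y),
#' and is bounded in `(0, 100 * max(conc)]`; an optimizer failure or a Kd
#' at the bounds is reported as non-convergence (no estimate).
#'
#' @param curve a [binding_curve()] with >= 3 distinct concentrations and
#'   at least one Y above `0.2 * max(Y)`.
#' @param model `"hyperbolic"` (default) or `"hill"`.
#' @param fix_ymax optionally fix the plateau (e.g. `1`); by default ymax
#'   is free, since gels rarely saturate at exactly 1.
#' @param average_replicates fit per-concentration mean Y instead of the
#'   raw points (default `FALSE`).
#' @return object of class `kd_estimate`: list with `kd`, `kd_stderr`,
#'   `ymax`, `hill_n`, `model`, `n_points`, `converged`, `status`.
#' @export
fit_kd <- function(curve, model = c("hyperbolic", "hill"), fix_ymax = NULL,
                   average_replicates = FALSE) {
  model <- match.arg(model)
  dat <- data.frame(conc = curve$conc, Y = curve$Y)
  if (average_replicates) {
    st <- saturation_table(curve)
    dat <- data.frame(conc = st$conc, Y = st$mean_Y)
  }
  fail <- function(status) {
    structure(list(kd = NA_real_, kd_stderr = NA_real_, ymax = NA_real_,
                   hill_n = NA_real_, model = model, n_points = nrow(dat),
                   converged = FALSE, status = status),
              class = "kd_estimate")
  }
  if (length(unique(dat$conc)) < 3) return(fail("fewer than 3 distinct concentrations"))
  ymax_obs <- max(dat$Y)
  if (!any(dat$Y > 0.2 * ymax_obs) || ymax_obs <= 0) {
    return(fail("no signal: all Y at or below baseline"))
  }
  mY <- vapply(split(dat$Y, dat$conc), mean, 0)
  st <- data.frame(conc = as.numeric(names(mY)), mean_Y = unname(mY))
  st <- st[order(st$conc), , drop = FALSE]
  half <- max(st$mean_Y) / 2
  above <- which(st$mean_Y >= half)
  kd0 <- if (length(above)) {
    i <- min(above)
    if (i == 1 || st$mean_Y[i] == st$mean_Y[i - 1]) st$conc[i] else {
      approx(st$mean_Y[(i - 1):i], st$conc[(i - 1):i], xout = half)$y
    }
  } else max(st$conc) / 2
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- max(dat$conc) / 2
  kd_hi <- 100 * max(dat$conc)
  lower <- c(kd = 1e-9); upper <- c(kd = kd_hi)
  start <- list(kd = kd0)
  if (is.null(fix_ymax)) {
    start$ymax <- max(ymax_obs, 0.1)
    lower <- c(lower, ymax = 1e-6); upper <- c(upper, ymax = 10)
  }
  if (model == "hill") {
    start$n <- 1
    lower <- c(lower, n = 0.1); upper <- c(upper, n = 10)
  }
  form <- if (model == "hill") {
    if (is.null(fix_ymax)) Y ~ ymax * conc^n / (kd^n + conc^n)
    else substitute(Y ~ F * conc^n / (kd^n + conc^n), list(F = fix_ymax))
  } else {
    if (is.null(fix_ymax)) Y ~ ymax * conc / (kd + conc)
    else substitute(Y ~ F * conc / (kd + conc), list(F = fix_ymax))
  }
  fit <- tryCatch(
    nls(stats::as.formula(form), data = dat, start = start,
        lower = lower, upper = upper, algorithm = "port",
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("optimizer failed"))
  co <- summary(fit)$coefficients
  kd <- co["kd", "Estimate"]
  if (kd <= lower[["kd"]] * 1.01 || kd >= kd_hi * 0.999) {
    return(fail("Kd hit optimizer bounds"))
  }
  structure(list(
    kd = kd,
    kd_stderr = co["kd", "Std. Error"],
    ymax = if (is.null(fix_ymax)) co["ymax", "Estimate"] else fix_ymax,
    hill_n = if (model == "hill") co["n", "Estimate"] else 1,
    model = model, n_points = nrow(dat), converged = TRUE, status = "ok"),
    class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Kd = %.3g +/- %.3g nM (ymax %.3f, n %.2f, %s, %d points)\n",
                x$kd, x$kd_stderr, x$ymax, x$hill_n, x$model, x$n_points))
  } else {
    cat(sprintf("Kd fit did not converge: %s\n", x$status))
  }
  invisible(x)
}

#' Read an EMSA intensity table
#'
#' @param path TSV with header columns `probe_id`, `conc_nM`,
#'   `replicate`, `I_T`, `I_C`.
#' @return named list of [binding_curve()] objects, one per probe.
#' @export
read_emsa_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "conc_nM", "replicate", "I_T", "I_C")
  miss <- setdiff(need, names(d))
  assert_that(length(miss) == 0,
              paste0("EMSA table missing column(s): ", paste(miss, collapse = ", ")))
  lapply(split(d, d$probe_id), function(p) {
    binding_curve(data.frame(conc = p$conc_nM, I_T = p$I_T, I_C = p$I_C,
                             replicate = p$replicate),
                  probe_id = p$probe_id[1])
  })
}
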