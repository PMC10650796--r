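## Functional-assay computations: BRET trace normalisation and AUC,
## 4PL dose-response fitting, fit comparison, BLI double referencing
## and global 1:1 Langmuir kinetic fitting, reporter-gene
## classification, and the split-luciferase competition readout.

#' Normalise kinetic traces to percent of the reference maximum
#'
#' Every trace is scaled by `100 / max(reference signal)` so that the
#' reference condition's maximum maps exactly to 100 (percent of
#' maximal agonist response). Idempotent on already-normalised
#' reference sets.
#'
#' @param traces long `data.frame` with columns `time`, `signal`,
#'   `condition`.
#' @param reference name of the reference condition (e.g. the maximal
#'   agonist response).
#' @return `traces` with `signal` rescaled; the scale factor is kept in
#'   attribute `scale`.
#' @export
normalize_percent_max <- function(traces, reference) {
  stopifnot(all(c("time", "signal", "condition") %in% names(traces)))
  ref <- traces$signal[traces$condition == reference]
  if (!length(ref)) stop("reference condition not present: ", reference)
  m <- max(ref)
  if (!is.finite(m) || m <= 0)
    stop("reference maximum must be positive")
  traces$signal <- traces$signal * (100 / m)
  attr(traces, "scale") <- 100 / m
  traces
}

#' Area under a kinetic trace after stimulation
#'
#' Trapezoidal integral of the signal over the post-stimulation window,
#' optionally after subtracting the mean pre-stimulation baseline.
#'
#' @param time,signal numeric vectors (time strictly increasing).
#' @param from_stimulation stimulation time; only `time >=
#'   from_stimulation` contributes to the area.
#' @param baseline_subtract subtract the mean signal at `time <
#'   from_stimulation` first (skipped when there are no
#'   pre-stimulation points).
#' @return The area (signal units x time units).
#' @examples
#' trace_auc(0:600, rep(100, 601))  # rectangle: 60,000
#' @export
trace_auc <- function(time, signal, from_stimulation = 0,
                      baseline_subtract = TRUE) {
  stopifnot(length(time) == length(signal),
            !is.unsorted(time, strictly = TRUE))
  post <- time >= from_stimulation
  if (sum(post) < 2L)
    stop("need at least two points after the stimulation time")
  if (baseline_subtract && any(!post))
    signal <- signal - mean(signal[!post])
  pracma::trapz(time[post], signal[post])
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (Emax - bottom) / (1 +
#' (EC50/x)^Hill)` with EC50 estimated on the log scale. `bottom`
#' and/or `hill` can be fixed (e.g. bottom 0 for baseline-subtracted
#' AUC responses, Hill 1 for a standard-slope fit); standard errors
#' come from the local curvature of the fit.
#'
#' @param dose doses in molar (> 0).
#' @param response responses (AUCs or endpoints), same length.
#' @param weights optional fitting weights.
#' @param fix_bottom fix the bottom asymptote at this value (NULL =
#'   free).
#' @param fix_hill fix the Hill slope at this value (NULL = free).
#' @return Object of class `fourpl_fit`: list with `coefficients`
#'   (bottom, emax, ec50, hill), `se` (NA for fixed parameters; the
#'   EC50 standard error is delta-method transformed from the log
#'   scale), `residual_rms`, `n`, and the underlying `nls` fit.
#' @export
fit_4pl <- function(dose, response, weights = NULL,
                    fix_bottom = NULL, fix_hill = NULL) {
  stopifnot(length(dose) == length(response), all(dose > 0))
  if (length(unique(dose)) < 5L)
    warning("fewer than 5 distinct doses; the fit may be poorly determined")
  df <- data.frame(x = dose, y = response)
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  half <- (min(response) + max(response)) / 2
  le0 <- log(dose[which.min(abs(response - half))])
  start <- list(top = max(response), le = le0)
  if (is.null(fix_bottom)) start$b <- min(response)
  if (is.null(fix_hill)) start$h <- 1
  b_term <- if (is.null(fix_bottom)) quote(b) else fix_bottom
  h_term <- if (is.null(fix_hill)) quote(h) else fix_hill
  form <- stats::as.formula(bquote(
    y ~ .(b_term) + (top - .(b_term)) / (1 + (exp(le) / x)^.(h_term))))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("4PL fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  ec50 <- exp(cf[["le"]])
  out <- list(
    coefficients = c(
      bottom = if (is.null(fix_bottom)) cf[["b"]] else fix_bottom,
      emax = cf[["top"]],
      ec50 = ec50,
      hill = if (is.null(fix_hill)) cf[["h"]] else fix_hill),
    se = c(bottom = if (is.null(fix_bottom)) se[["b"]] else NA_real_,
           emax = se[["top"]],
           ec50 = ec50 * se[["le"]],
           hill = if (is.null(fix_hill)) se[["h"]] else NA_real_),
    residual_rms = sqrt(mean(stats::resid(fit)^2)),
    n = nrow(df),
    fit = fit)
  class(out) <- "fourpl_fit"
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Four-parameter logistic fit (n =", x$n, ")\n")
  print(rbind(estimate = x$coefficients, se = x$se))
  cat("residual RMS:", signif(x$residual_rms, 4), "\n")
  invisible(x)
}

#' Compare two dose-response fits
#'
#' Reports the EC50 fold-shift (control / treated, so a left shift
#' gives a value > 1), the Emax ratio (treated / control), the shift in
#' log10 EC50, and whether the approximate 95% confidence intervals of
#' each parameter overlap between the two fits.
#'
#' @param control,treated `fourpl_fit` objects.
#' @return List with `ec50_fold_shift`, `delta_log10_ec50`,
#'   `emax_ratio`, `ec50_ci_overlap`, `emax_ci_overlap`.
#' @export
compare_fits <- function(control, treated) {
  stopifnot(inherits(control, "fourpl_fit"), inherits(treated, "fourpl_fit"))
  ci <- function(fit, par) {
    e <- fit$coefficients[[par]]; s <- fit$se[[par]]
    if (is.na(s)) c(e, e) else c(e - 1.96 * s, e + 1.96 * s)
  }
  overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  list(
    ec50_fold_shift = control$coefficients[["ec50"]] /
      treated$coefficients[["ec50"]],
    delta_log10_ec50 = log10(treated$coefficients[["ec50"]]) -
      log10(control$coefficients[["ec50"]]),
    emax_ratio = treated$coefficients[["emax"]] /
      control$coefficients[["emax"]],
    ec50_ci_overlap = overlaps(ci(control, "ec50"), ci(treated, "ec50")),
    emax_ci_overlap = overlaps(ci(control, "emax"), ci(treated, "emax")))
}

#' Double-reference a BLI sensorgram
#'
#' Subtracts the non-relevant-control sensorgram and the blank from the
#' sample (`referenced = sample - nr_control - blank`), then optionally
#' re-zeroes the result at the association start.
#'
#' @param sample,nr_control,blank `data.frame`s with `time` and
#'   `response` on identical time grids.
#' @param rezero_at time at which the referenced response is re-zeroed
#'   (NULL to skip).
#' @return `data.frame` with `time` and the referenced `response`.
#' @export
bli_double_subtract <- function(sample, nr_control, blank,
                                rezero_at = 0) {
  if (!isTRUE(all.equal(sample$time, nr_control$time)) ||
      !isTRUE(all.equal(sample$time, blank$time)))
    stop("sensorgrams must share an identical time grid")
  ref <- sample$response - nr_control$response - blank$response
  if (!is.null(rezero_at)) {
    i0 <- which.min(abs(sample$time - rezero_at))
    ref <- ref - ref[i0]
  }
  data.frame(time = sample$time, response = ref)
}

#' Global 1:1 Langmuir fit of referenced sensorgrams
#'
#' Fits association and dissociation phases of all concentrations
#' jointly, sharing `kon`, `koff` and `Rmax` across curves (rates on
#' the log scale). Initial values are data-driven: `koff` from the
#' log-linear decay of the highest-concentration dissociation, `Rmax`
#' and `KD` from the concentration dependence of the association
#' plateaus, `kon = koff / KD`.
#'
#' @param data long `data.frame` with `conc` (molar), `time` (s) and
#'   `response`, covering at least 3 concentrations.
#' @param t_assoc association phase duration (s); larger times are
#'   treated as dissociation.
#' @return Object of class `langmuir_fit`: list with `kon`, `koff`,
#'   `rmax`, `kd` (= koff/kon), `se` (delta-method rate SEs),
#'   `residual_rms` and the underlying `nls` fit.
#' @export
fit_langmuir <- function(data, t_assoc) {
  stopifnot(all(c("conc", "time", "response") %in% names(data)))
  concs <- sort(unique(data$conc))
  if (length(concs) < 3L)
    stop("need at least 3 analyte concentrations for a global fit")
  top_c <- max(concs)
  dis <- data[data$conc == top_c & data$time > t_assoc &
                data$response > 0, ]
  koff0 <- if (nrow(dis) >= 3L)
    max(1e-6, -unname(stats::coef(stats::lm(log(response) ~ time,
                                            data = dis))[2L]))
  else 1e-3
  plateaus <- vapply(concs, function(cc) {
    a <- data[data$conc == cc & data$time <= t_assoc, ]
    mean(utils::tail(a$response[order(a$time)], 3L))
  }, numeric(1L))
  # Req(C) = Rmax C / (C + KD): linearise as 1/Req ~ 1/C
  pos <- plateaus > 0
  kd0 <- top_c
  rmax0 <- max(data$response) * 1.2
  if (sum(pos) >= 2L) {
    lf <- stats::lm(I(1 / plateaus[pos]) ~ I(1 / concs[pos]))
    if (all(is.finite(stats::coef(lf))) && stats::coef(lf)[1L] > 0) {
      rmax0 <- unname(1 / stats::coef(lf)[1L])
      kd0 <- unname(max(1e-12, stats::coef(lf)[2L] / stats::coef(lf)[1L]))
    }
  }
  kon0 <- koff0 / kd0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ langmuir_response(time, conc, exp(lkon), exp(lkoff),
                                   rmax, t_assoc),
      data = data,
      start = list(lkon = log(kon0), lkoff = log(koff0), rmax = rmax0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Langmuir fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  kon <- exp(cf[["lkon"]]); koff <- exp(cf[["lkoff"]])
  out <- list(kon = kon, koff = koff, rmax = cf[["rmax"]],
              kd = koff / kon,
              se = c(kon = kon * se[["lkon"]], koff = koff * se[["lkoff"]],
                     rmax = se[["rmax"]]),
              residual_rms = sqrt(mean(stats::resid(fit)^2)),
              fit = fit)
  class(out) <- "langmuir_fit"
  out
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("1:1 Langmuir global fit\n")
  cat(sprintf("  kon  = %.4g 1/(M s)\n  koff = %.4g 1/s\n", x$kon, x$koff))
  cat(sprintf("  Rmax = %.4g RU\n  KD   = %.4g M (%.3g nM)\n",
              x$rmax, x$kd, x$kd * 1e9))
  invisible(x)
}

#' Classify reporter-gene candidates against the non-relevant control
#'
#' Expresses each candidate's luminescence as a percentage of the
#' non-relevant (NR) control mean and classifies it as a positive
#' modulator when `percent - 100 > margin * spread`, negative when
#' `percent - 100 < -margin * spread`, and neutral otherwise, where
#' `spread` is the standard deviation of the candidate's replicate
#' percentages.
#'
#' @param rlu long `data.frame` with columns `candidate` and `rlu`
#'   (replicate luminescence values).
#' @param nr_control name of the NR control candidate (its own percent
#'   is 100 by construction).
#' @param margin multiple of the replicate spread used as the
#'   neutrality band (default 2).
#' @return `data.frame` per candidate: `candidate`, `percent`,
#'   `spread`, `class`.
#' @export
classify_reporter <- function(rlu, nr_control = "NR", margin = 2) {
  stopifnot(all(c("candidate", "rlu") %in% names(rlu)))
  if (!nr_control %in% rlu$candidate)
    stop("NR control replicates not present: ", nr_control)
  nr_mean <- mean(rlu$rlu[rlu$candidate == nr_control])
  if (nr_mean <= 0) stop("NR control mean must be positive")
  per <- split(100 * rlu$rlu / nr_mean, rlu$candidate)
  out <- do.call(rbind, lapply(names(per), function(id) {
    p <- per[[id]]
    spread <- if (length(p) > 1L) stats::sd(p) else 0
    delta <- mean(p) - 100
    cls <- if (delta > margin * spread) "positive"
    else if (delta < -margin * spread) "negative" else "neutral"
    data.frame(candidate = id, percent = mean(p), spread = spread,
               class = cls, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Split-luciferase competition verdict from plateau luminescence
#'
#' Compares steady-state luminescence plateaus with and without the
#' putative competitor: per-replicate plateaus are the means over the
#' trailing `plateau_fraction` of each trace, the readout is the ratio
#' of plateau means (competitor / NR control) with a delta-method 95%
#' confidence interval, and the verdict is `"no_competition"` when the
#' interval contains 1.
#'
#' @param traces long `data.frame` with `time`, `signal`, `group`
#'   (`"competitor"` or `"nr_control"`) and `replicate`.
#' @param plateau_fraction trailing fraction of each trace averaged as
#'   the plateau (default 0.2).
#' @return List with `ratio`, `ci` (length 2), and `verdict`
#'   (`"competition"` / `"no_competition"`).
#' @export
nanobit_competition <- function(traces, plateau_fraction = 0.2) {
  stopifnot(all(c("time", "signal", "group", "replicate") %in%
                  names(traces)),
            all(c("competitor", "nr_control") %in% traces$group))
  plateau <- function(d) {
    d <- d[order(d$time), ]
    k <- max(2L, ceiling(nrow(d) * plateau_fraction))
    mean(utils::tail(d$signal, k))
  }
  pl <- lapply(split(traces, list(traces$group, traces$replicate),
                     drop = TRUE), plateau)
  grp <- sub("\\..*$", "", names(pl))
  comp <- unlist(pl[grp == "competitor"])
  nr <- unlist(pl[grp == "nr_control"])
  ratio <- mean(comp) / mean(nr)
  se_m <- function(x) stats::sd(x) / sqrt(length(x))
  se_ratio <- ratio * sqrt((se_m(comp) / mean(comp))^2 +
                             (se_m(nr) / mean(nr))^2)
  ci <- ratio + c(-1.96, 1.96) * se_ratio
  list(ratio = ratio, ci = ci,
       verdict = if (ci[1] <= 1 && 1 <= ci[2]) "no_competition"
       else "competition")
}
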