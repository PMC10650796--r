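ref_trace <- function(amp = 1, seed = 1, noise = 0)
  cbind(simulate_bret_trace(amplitude = amp, noise_sd = noise, seed = seed),
        condition = "x")

test_that("percent-of-maximum normalisation anchors the reference at 100", {
  tr <- rbind(transform(ref_trace(1), condition = "ref"),
              transform(ref_trace(1.8), condition = "prc1"))
  norm <- normalize_percent_max(tr, "ref")
  expect_equal(max(norm$signal[norm$condition == "ref"]), 100)
  # a trace identical to the reference normalises identically
  expect_equal(norm$signal[norm$condition == "ref"],
               normalize_percent_max(
                 transform(ref_trace(1), condition = "ref"),
                 "ref")$signal)
  # 1.8x the reference amplitude -> max ~ 180 (same rise shape)
  expect_equal(max(norm$signal[norm$condition == "prc1"]), 180,
               tolerance = 1e-6)
  # idempotent on an already-normalised set
  again <- normalize_percent_max(norm, "ref")
  expect_equal(again$signal, norm$signal)
  bad <- transform(ref_trace(1), condition = "ref", signal = 0)
  expect_error(normalize_percent_max(bad, "ref"), "positive")
})

test_that("AUC follows rectangle / triangle arithmetic", {
  t <- 0:600
  expect_equal(trace_auc(t, rep(0, 601)), 0)
  expect_equal(trace_auc(t, rep(100, 601)), 60000)
  expect_equal(trace_auc(t, 100 * t / 600), 30000)
})

test_that("AUC is linear and additive over concatenated windows", {
  set.seed(9)
  t <- seq(0, 1200, by = 60)
  y <- runif(length(t), 0, 50)
  expect_equal(trace_auc(t, 3.7 * y, baseline_subtract = FALSE),
               3.7 * trace_auc(t, y, baseline_subtract = FALSE))
  left <- t <= 600
  expect_equal(trace_auc(t[left], y[left], baseline_subtract = FALSE) +
                 trace_auc(t[t >= 600], y[t >= 600],
                           baseline_subtract = FALSE),
               trace_auc(t, y, baseline_subtract = FALSE))
  # pre-stimulation baseline is subtracted
  y2 <- c(rep(10, 5), rep(110, 16))
  t2 <- seq(0, 1200, by = 60)
  expect_equal(trace_auc(t2, y2, from_stimulation = 300),
               trace_auc(t2, y2 - 10, from_stimulation = 300,
                         baseline_subtract = FALSE))
})

test_that("noiseless 4PL fits recover the generating parameters", {
  doses <- 10^seq(-9.5, -6.5, by = 0.5)
  truth <- c(bottom = 0, emax = 100, ec50 = 1e-9, hill = 1)
  dd <- simulate_doseresponse(doses, truth["bottom"], truth["emax"],
                              truth["ec50"], truth["hill"],
                              n_replicates = 1, noise_sd = 0)
  fit <- fit_4pl(dd$dose, dd$response)
  expect_equal(fit$coefficients[c("emax", "ec50", "hill")],
               truth[c("emax", "ec50", "hill")], tolerance = 1e-6)
  expect_lt(abs(fit$coefficients[["bottom"]]), 1e-4)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("fit comparison reproduces the printed potency and efficacy shifts", {
  doses <- 10^seq(-9.5, -6.5, by = 0.5)
  mk <- function(emax, ec50) {
    dd <- simulate_doseresponse(doses, 0, emax, ec50, 1,
                                n_replicates = 1, noise_sd = 0)
    fit_4pl(dd$dose, dd$response, fix_bottom = 0, fix_hill = 1)
  }
  ctrl <- mk(14.11, 0.63e-9)
  prc1 <- mk(34.52, 0.15e-9)
  cmp <- compare_fits(ctrl, prc1)
  expect_equal(round(cmp$emax_ratio, 1), 2.4)       # 34.52 / 14.11
  expect_equal(round(cmp$ec50_fold_shift, 1), 4.2)  # 0.63 / 0.15
  same <- compare_fits(ctrl, ctrl)
  expect_equal(same$emax_ratio, 1)
  expect_equal(same$ec50_fold_shift, 1)
})

test_that("double referencing removes control and blank signals", {
  t <- 0:250
  lang <- data.frame(time = t,
                     response = langmuir_response(t, 5e-8, 3.19e4,
                                                  1.59e-3, 1, 100))
  drift <- data.frame(time = t, response = 0.002 * t)
  nr <- data.frame(time = t, response = 0.05 + 0 * t)

  # sample = nr + blank exactly -> all zero
  s0 <- data.frame(time = t, response = nr$response + drift$response)
  expect_true(all(abs(bli_double_subtract(s0, nr, drift)$response) < 1e-12))

  # zero references -> identity
  zero <- data.frame(time = t, response = 0 * t)
  expect_equal(bli_double_subtract(lang, zero, zero)$response,
               lang$response)

  # additive drift equal to the blank is removed, Langmuir recovered
  sample <- data.frame(time = t,
                       response = lang$response + drift$response +
                         nr$response)
  ref <- bli_double_subtract(sample, nr, drift)
  expect_equal(ref$response, lang$response, tolerance = 1e-10)
  expect_error(bli_double_subtract(lang, nr[-1, ], drift), "time grid")
})

test_that("noiseless global Langmuir fits recover rates to 1e-6", {
  kon <- 3.19e4; koff <- 1.59e-3
  tr <- simulate_bli(kon, koff, 1.0, c(12.5, 25, 50, 100, 200) * 1e-9,
                     noise_sd = 0)
  fit <- fit_langmuir(tr, t_assoc = 100)
  expect_equal(fit$kon, kon, tolerance = 1e-6)
  expect_equal(fit$koff, koff, tolerance = 1e-6)
  # KD identity holds to machine precision
  expect_equal(fit$kd, fit$koff / fit$kon, tolerance = 1e-12)
})

test_that("Langmuir rates survive 2% noise: KD within 15% of truth", {
  kon <- 3.19e4; koff <- 1.59e-3; kd <- koff / kon
  tr <- simulate_bli(kon, koff, 1.0, c(12.5, 25, 50, 100, 200) * 1e-9,
                     noise_sd = 0.02, seed = 19)
  fit <- fit_langmuir(tr, t_assoc = 100)
  expect_lt(abs(fit$kd - kd) / kd, 0.15)
})

test_that("reporter candidates classify against the NR control", {
  set.seed(10)
  rlu <- data.frame(
    candidate = rep(c("NR", "same", "up", "down"), each = 6),
    rlu = c(rnorm(6, 1000, 20), rnorm(6, 1000, 20),
            rnorm(6, 2000, 20), rnorm(6, 500, 20)))
  res <- classify_reporter(rlu, nr_control = "NR")
  expect_equal(res$class[res$candidate == "NR"], "neutral")
  expect_equal(round(res$percent[res$candidate == "NR"]), 100)
  expect_equal(res$class[res$candidate == "same"], "neutral")
  expect_equal(res$class[res$candidate == "up"], "positive")
  expect_equal(res$class[res$candidate == "down"], "negative")
})

test_that("plateau competition readout distinguishes competitors", {
  mk_traces <- function(amp_comp, noise = 0.01, n = 6, seed = 30) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n), function(r) {
      rbind(
        transform(simulate_bret_trace(amplitude = 1, noise_sd = noise,
                                      seed = seed + r),
                  group = "nr_control", replicate = r),
        transform(simulate_bret_trace(amplitude = amp_comp,
                                      noise_sd = noise, seed = seed + 100 + r),
                  group = "competitor", replicate = r))
    }))
  }
  names(mk_traces(1))  # columns: time, signal, group, replicate
  same <- nanobit_competition(mk_traces(1, noise = 0))
  expect_equal(same$ratio, 1, tolerance = 1e-12)
  expect_equal(same$verdict, "no_competition")

  comp <- nanobit_competition(mk_traces(0.3))
  expect_equal(comp$verdict, "competition")
  expect_lt(comp$ratio, 0.5)

  # equal plateaus with noise at n = 6: no competition called
  null <- nanobit_competition(mk_traces(1, noise = 0.02))
  expect_equal(null$verdict, "no_competition")
})
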