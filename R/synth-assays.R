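## Synthetic assay inputs: epitope predictions, BLI sensorgrams, BRET
## kinetic traces and dose-response data, all with known ground truth.

#' Four-parameter logistic response
#'
#' `y = bottom + (top - bottom) / (1 + (ec50 / x)^hill)`.
#'
#' @param x dose (same units as `ec50`, typically molar).
#' @param bottom,top,ec50,hill model parameters; `top` is the maximal
#'   response (Emax), `ec50` the half-maximal effective dose, `hill`
#'   the slope factor.
#' @return Numeric vector of responses.
#' @export
fourpl <- function(x, bottom, top, ec50, hill)
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)

#' 1:1 Langmuir binding model
#'
#' Association at analyte concentration `conc`:
#' `R(t) = Req (1 - exp(-kobs t))` with `kobs = kon * conc + koff` and
#' `Req = rmax * conc / (conc + KD)`, `KD = koff / kon`. Dissociation
#' from the response at the end of association `R0`:
#' `R(t) = R0 exp(-koff (t - t_assoc))`.
#'
#' @param t time in seconds (from the start of association).
#' @param conc analyte concentration in molar.
#' @param kon association rate constant, 1/(M s).
#' @param koff dissociation rate constant, 1/s.
#' @param rmax maximal binding response, response units.
#' @param t_assoc association phase duration in seconds; times beyond
#'   it are treated as dissociation.
#' @return Numeric vector of responses.
#' @export
langmuir_response <- function(t, conc, kon, koff, rmax, t_assoc) {
  stopifnot(kon > 0, koff > 0)
  kd <- koff / kon
  req <- rmax * conc / (conc + kd)
  kobs <- kon * conc + koff
  r0 <- req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc,
         req * (1 - exp(-kobs * t)),
         r0 * exp(-koff * (t - t_assoc)))
}

#' Simulate BLI sensorgrams under a 1:1 binding model
#'
#' One association/dissociation trace per analyte concentration with
#' additive Gaussian noise; `noise_sd = 0` reproduces the
#' [langmuir_response()] model exactly.
#'
#' @param kon,koff,rmax generating Langmuir parameters (see
#'   [langmuir_response()]).
#' @param concentrations analyte concentrations in molar.
#' @param t_assoc,t_dissoc association / dissociation durations (s).
#' @param dt sampling interval (s).
#' @param noise_sd additive Gaussian noise SD in response units.
#' @param seed integer RNG seed.
#' @return Long `data.frame`: `conc`, `time`, `response`, `phase`.
#' @examples
#' tr <- simulate_bli(3.19e4, 1.59e-3, 1, c(25, 50, 100) * 1e-9)
#' @export
simulate_bli <- function(kon, koff, rmax, concentrations,
                         t_assoc = 100, t_dissoc = 150, dt = 1,
                         noise_sd = 0, seed = 1L) {
  stopifnot(all(concentrations > 0))
  set.seed(seed)
  tgrid <- seq(0, t_assoc + t_dissoc, by = dt)
  out <- lapply(concentrations, function(cc) {
    r <- langmuir_response(tgrid, cc, kon, koff, rmax, t_assoc)
    if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
    data.frame(conc = cc, time = tgrid, response = r,
               phase = ifelse(tgrid <= t_assoc, "association",
                              "dissociation"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a BRET-style kinetic trace
#'
#' A flat baseline before the stimulation time followed by a saturating
#' mono-exponential rise, emulating a ligand-induced BRET ratio recorded
#' at regular intervals. With `noise_sd = 0` the trace is exactly
#' `baseline + amplitude * (1 - exp(-rate * (t - stim_time)))` after
#' stimulation.
#'
#' @param times sampling times (s), strictly increasing.
#' @param amplitude plateau amplitude above baseline.
#' @param rate rise rate constant (1/s).
#' @param stim_time stimulation (injection) time (s).
#' @param baseline pre-stimulation signal level.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return `data.frame` with `time` and `signal`.
#' @export
simulate_bret_trace <- function(times = seq(0, 3600, by = 60),
                                amplitude = 1, rate = 1 / 300,
                                stim_time = 300, baseline = 0,
                                noise_sd = 0, seed = 1L) {
  stopifnot(!is.unsorted(times, strictly = TRUE))
  set.seed(seed)
  sig <- ifelse(times <= stim_time, baseline,
                baseline + amplitude * (1 - exp(-rate * (times - stim_time))))
  if (noise_sd > 0) sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
  data.frame(time = times, signal = sig)
}

#' Simulate replicated dose-response data from a 4PL model
#'
#' @param doses dose grid in molar.
#' @param bottom,top,ec50,hill generating 4PL parameters (see
#'   [fourpl()]).
#' @param n_replicates replicates per dose.
#' @param noise_sd additive Gaussian noise SD in response units.
#' @param seed integer RNG seed.
#' @return `data.frame` with `dose`, `replicate`, `response`.
#' @export
simulate_doseresponse <- function(doses, bottom, top, ec50, hill = 1,
                                  n_replicates = 4L, noise_sd = 0,
                                  seed = 1L) {
  stopifnot(all(doses > 0), ec50 > 0, top >= bottom)
  set.seed(seed)
  d <- rep(doses, each = n_replicates)
  y <- fourpl(d, bottom, top, ec50, hill)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  data.frame(dose = d,
             replicate = rep(seq_len(n_replicates), times = length(doses)),
             response = y)
}

#' Simulate tiered epitope predictions with a planted site structure
#'
#' Antibodies are partitioned across `n_sites` disjoint residue blocks
#' on the antigen; each antibody's predicted epitope is a random subset
#' of its site's block, large enough that any two same-site antibodies
#' share more than 30% of their residues while different-site pairs
#' share none. Residue confidence tiers (`very_high` / `high` /
#' `medium`) are assigned at random. A pairwise similarity score table
#' correlated with shared-site membership is generated alongside
#' (same-site pairs score 55-95, different-site pairs 5-25).
#'
#' @param n_antibodies number of antibodies (>= `n_sites`).
#' @param n_residues length of the antigen (residues are indexed
#'   1..`n_residues`).
#' @param n_sites number of planted epitope sites.
#' @param site_width residues per site block.
#' @param epitope_size predicted residues per antibody (must exceed
#'   `site_width / 2` so that same-site overlaps exceed 0.3 by
#'   construction).
#' @param seed integer RNG seed.
#' @return List with `predictions` (long `data.frame`: `antibody_id`,
#'   `residue`, `tier`), `similarity` (symmetric numeric matrix), and
#'   `site` (named integer vector, the planted assignment).
#' @export
simulate_epitopes <- function(n_antibodies, n_residues = 350L,
                              n_sites = 3L, site_width = 20L,
                              epitope_size = 15L, seed = 1L) {
  if (n_sites > n_antibodies)
    stop("n_sites must not exceed n_antibodies")
  if (n_sites * site_width > n_residues)
    stop("antigen too short for the requested disjoint sites")
  if ((2 * epitope_size - site_width) / epitope_size <= 0.3)
    stop("epitope_size too small to guarantee same-site overlap > 0.3")
  set.seed(seed)
  ids <- sprintf("ab%02d", seq_len(n_antibodies))
  site <- stats::setNames(rep_len(seq_len(n_sites), n_antibodies), ids)
  starts <- round(seq(1, n_residues - site_width + 1,
                      length.out = n_sites))
  tiers <- c("very_high", "high", "medium")
  preds <- lapply(seq_len(n_antibodies), function(i) {
    block <- seq.int(starts[site[i]], length.out = site_width)
    res <- sort(sample(block, epitope_size))
    data.frame(antibody_id = ids[i], residue = res,
               tier = sample(tiers, epitope_size, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  sim <- matrix(0, n_antibodies, n_antibodies, dimnames = list(ids, ids))
  for (i in seq_len(n_antibodies))
    for (j in seq_len(n_antibodies)) {
      if (j <= i) next
      sim[i, j] <- sim[j, i] <- if (site[i] == site[j])
        stats::runif(1, 55, 95) else stats::runif(1, 5, 25)
    }
  diag(sim) <- 100
  list(predictions = do.call(rbind, preds), similarity = sim, site = site)
}
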