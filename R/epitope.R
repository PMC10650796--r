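## Virtual epitope binning: pairwise overlap of predicted epitopes,
## similarity-score probability tiers, and the incoherence matrix
## contrasting sequence/structure similarity with predicted overlap.

.split_predictions <- function(predictions) {
  stopifnot(all(c("antibody_id", "residue", "tier") %in%
                  names(predictions)))
  bad <- setdiff(unique(predictions$tier),
                 c("very_high", "high", "medium"))
  if (length(bad))
    stop("unknown confidence tier(s): ", paste(bad, collapse = ", "))
  split(predictions$residue, predictions$antibody_id)
}

#' Epitope overlap ratio between two predictions
#'
#' Number of residues predicted (at very-high, high or medium
#' confidence, all counted equally) to belong to both epitopes, divided
#' by the larger epitope's residue count:
#' `|A intersect B| / max(|A|, |B|)`.
#'
#' @param res_a,res_b integer vectors of predicted epitope residue
#'   indices for the two antibodies.
#' @return Overlap ratio in `[0, 1]`.
#' @export
overlap_ratio <- function(res_a, res_b) {
  res_a <- unique(res_a); res_b <- unique(res_b)
  if (!length(res_a) || !length(res_b))
    stop("overlap is undefined for an empty epitope prediction")
  length(intersect(res_a, res_b)) / max(length(res_a), length(res_b))
}

#' Pairwise epitope overlap matrix
#'
#' @param predictions long `data.frame` (`antibody_id`, `residue`,
#'   `tier`) of per-antibody epitope predictions.
#' @return Symmetric matrix of overlap ratios with unit diagonal.
#' @export
overlap_matrix <- function(predictions) {
  sets <- .split_predictions(predictions)
  ids <- names(sets)
  n <- length(ids)
  O <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1L)
    for (i in 1:(n - 1L))
      for (j in (i + 1L):n)
        O[i, j] <- O[j, i] <- overlap_ratio(sets[[i]], sets[[j]])
  O
}

#' Competition call from an overlap ratio
#'
#' Two antibodies are considered in competition for the same epitope
#' when their overlap ratio is strictly greater than the threshold
#' (default 0.3).
#'
#' @param overlap overlap ratio(s) in `[0, 1]` (scalar or matrix).
#' @param threshold strict competition threshold.
#' @return Logical of the same shape as `overlap`.
#' @export
competition_call <- function(overlap, threshold = 0.3) {
  if (any(overlap < 0 | overlap > 1, na.rm = TRUE))
    stop("overlap ratios must lie in [0, 1]")
  overlap > threshold
}

#' Tiered probability of shared epitope from a similarity score
#'
#' Similarity above 50 maps to a 0.95 probability of sharing the
#' epitope; scores from 30 to 50 map to 0.75; lower scores are
#' unassessed (`NA`).
#'
#' @param score non-negative similarity score(s).
#' @return Numeric vector: 0.95, 0.75 or `NA` ("unassessed").
#' @export
similarity_probability <- function(score) {
  if (any(score < 0, na.rm = TRUE))
    stop("similarity scores must be non-negative")
  ifelse(score > 50, 0.95, ifelse(score >= 30, 0.75, NA_real_))
}

#' Incoherence matrix between similarity and epitope overlap
#'
#' The similarity matrix is min-max normalised over its off-diagonal
#' entries (self-similarity would otherwise saturate the maximum) and
#' the epitope overlap is subtracted:
#' `I = (S - min S) / (max S - min S) - O`. An incoherence of 1 means a
#' pair of identical antibodies predicted to bind disjoint epitopes.
#' Pairs whose incoherence exceeds `flag_threshold` are flagged.
#'
#' @param similarity symmetric similarity score matrix.
#' @param overlap symmetric overlap matrix covering the same antibody
#'   set (same dimnames).
#' @param flag_threshold incoherence level above which a pair is
#'   flagged (default 0.5).
#' @return List with `incoherence` (matrix, diagonal `NA`),
#'   `n_flagged` (count of flagged unordered pairs) and `flagged`
#'   (`data.frame` of the flagged pairs and their incoherence).
#' @export
incoherence_matrix <- function(similarity, overlap, flag_threshold = 0.5) {
  if (!identical(dimnames(similarity), dimnames(overlap)))
    stop("similarity and overlap matrices must cover the same antibodies")
  off <- row(similarity) != col(similarity)
  rng <- range(similarity[off])
  if (rng[1] == rng[2])
    stop("degenerate normalisation: all off-diagonal similarities equal")
  s_norm <- (similarity - rng[1]) / (rng[2] - rng[1])
  inc <- s_norm - overlap
  diag(inc) <- NA_real_
  up <- which(upper.tri(inc) & inc > flag_threshold, arr.ind = TRUE)
  flagged <- data.frame(
    antibody_a = rownames(inc)[up[, 1L]],
    antibody_b = colnames(inc)[up[, 2L]],
    incoherence = inc[up],
    stringsAsFactors = FALSE)
  list(incoherence = inc, n_flagged = nrow(flagged), flagged = flagged)
}

#' Connected components of the competition graph
#'
#' Builds the pairwise competition graph (edges where
#' [competition_call()] is true) from an overlap matrix and returns its
#' connected components -- the virtual epitope bins.
#'
#' @param overlap overlap matrix from [overlap_matrix()].
#' @param threshold competition threshold passed to
#'   [competition_call()].
#' @return Named integer vector of component labels (1-based).
#' @export
competition_components <- function(overlap, threshold = 0.3) {
  adj <- competition_call(overlap, threshold)
  diag(adj) <- TRUE
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cur
      reach <- colSums(matrix(adj[frontier, , drop = FALSE],
                              nrow = length(frontier))) > 0
      nxt <- which(reach)
      frontier <- setdiff(nxt, which(!is.na(comp)))
    }
  }
  stats::setNames(comp, rownames(overlap))
}
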