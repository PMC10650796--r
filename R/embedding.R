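## Kmer encoding of CDR signatures and 2D UMAP embedding of the
## repertoire, with candidate overlay and a cohesion summary.

#' Encode signatures as sparse kmer count vectors
#'
#' Counts overlapping amino-acid kmers of length `k` in each signature.
#' Only kmers observed in the input are materialised (the full
#' 20^k space would be prohibitively wide). For every signature of
#' length `L >= k` the row sum is exactly `L - k + 1`; shorter
#' signatures yield an all-zero row with a warning.
#'
#' @param signatures character vector of CDR signatures (names or the
#'   strings themselves become row names).
#' @param k kmer length (default 5).
#' @return A `Matrix::sparseMatrix` (signatures x observed kmers) of
#'   counts, with attribute `k`.
#' @examples
#' m <- kmer_encode(c("AAAAAA", "AAAAC"), k = 5)
#' Matrix::rowSums(m)
#' @export
kmer_encode <- function(signatures, k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  n <- length(signatures)
  rn <- if (!is.null(names(signatures))) names(signatures) else signatures
  lens <- nchar(signatures)
  if (any(lens < k))
    warning(sum(lens < k), " signature(s) shorter than k = ", k,
            " encoded as all-zero rows")
  kmers_by_row <- lapply(seq_len(n), function(i) {
    L <- lens[i]
    if (L < k) return(character(0))
    substring(signatures[i], 1:(L - k + 1L), k:L)
  })
  flat <- unlist(kmers_by_row, use.names = FALSE)
  all_kmers <- sort(unique(flat))
  # duplicated (i, j) pairs are summed by sparseMatrix
  m <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lengths(kmers_by_row)),
    j = match(flat, all_kmers),
    x = rep(1, length(flat)),
    dims = c(n, length(all_kmers)),
    dimnames = list(rn, all_kmers))
  attr(m, "k") <- as.integer(k)
  m
}

#' Embed a kmer matrix into two dimensions with UMAP
#'
#' Projects kmer count vectors into a low-dimensional space in which
#' closely related sequences are neighbours. Deterministic under a
#' fixed seed (single-threaded optimisation); identical kmer rows map
#' to coincident or near-coincident points.
#'
#' @param kmat kmer matrix from [kmer_encode()].
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param n_components embedding dimensionality (default 2).
#' @param metric distance metric (default Euclidean).
#' @param seed integer RNG seed (default 42).
#' @return Numeric matrix (rows = signatures, columns `x`, `y`, ...)
#'   with the embedding parameters stored in attribute `params`.
#' @export
embed_signatures <- function(kmat, n_neighbors = 15L, n_components = 2L,
                             metric = "euclidean", seed = 42L) {
  if (nrow(kmat) < n_neighbors + 1L)
    stop("need at least n_neighbors + 1 signatures to embed")
  set.seed(seed)
  coords <- uwot::umap(as.matrix(kmat), n_neighbors = n_neighbors,
                       n_components = n_components, metric = metric,
                       n_threads = 1, n_sgd_threads = 0)
  rownames(coords) <- rownames(kmat)
  colnames(coords) <- c("x", "y", paste0("dim", seq_len(n_components)))[
    seq_len(n_components)]
  attr(coords, "params") <- list(k = attr(kmat, "k"),
                                 n_neighbors = n_neighbors,
                                 n_components = n_components,
                                 metric = metric, seed = seed)
  coords
}

#' Overlay selected candidates on a repertoire embedding
#'
#' Flags candidate outliers: a candidate whose nearest selected peer in
#' the embedding lies further away than the `background_quantile`
#' quantile of the background spacing is reported as an outlier. The
#' background spacing is the distance from each embedded point to its
#' k-th nearest neighbour with `k = ceiling(n_points / n_selected)` --
#' the spacing the candidates would show if they were a random subset
#' of the repertoire -- so the rule is insensitive to how sparsely the
#' candidates sample their neighbourhood. With a single candidate there
#' are no peers and no outliers.
#'
#' @param embedding matrix from [embed_signatures()].
#' @param selected character vector of selected signatures (must all be
#'   present in the embedding).
#' @param background_quantile quantile of background nearest-neighbour
#'   distances used as the outlier cutoff (default 0.99).
#' @return `data.frame` per candidate: `signature`, `x`, `y`,
#'   `nn_selected_dist`, `outlier`; the cutoff is kept in attribute
#'   `cutoff`.
#' @export
overlay_candidates <- function(embedding, selected,
                               background_quantile = 0.99) {
  missing <- setdiff(selected, rownames(embedding))
  if (length(missing))
    stop("selected signatures absent from the embedding: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  sel_xy <- embedding[selected, 1:2, drop = FALSE]
  all_xy <- embedding[, 1:2, drop = FALSE]
  k <- max(1L, ceiling(nrow(all_xy) / max(1L, length(selected))))
  dall <- as.matrix(stats::dist(all_xy))
  diag(dall) <- Inf
  bg_k <- apply(dall, 1L, function(r) sort(r, partial = k)[k])
  cutoff <- stats::quantile(bg_k, background_quantile, names = FALSE)
  if (length(selected) < 2L) {
    nn_sel <- rep(NA_real_, length(selected))
    outlier <- rep(FALSE, length(selected))
  } else {
    dsel <- as.matrix(stats::dist(sel_xy))
    diag(dsel) <- Inf
    nn_sel <- apply(dsel, 1L, min)
    outlier <- nn_sel > cutoff
  }
  structure(data.frame(signature = selected,
                       x = sel_xy[, 1L], y = sel_xy[, 2L],
                       nn_selected_dist = nn_sel, outlier = outlier,
                       row.names = NULL, stringsAsFactors = FALSE),
            cutoff = cutoff)
}
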