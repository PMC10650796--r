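## Panning count dynamics and synthetic amplicon reads.

#' Simulate round-over-round panning counts
#'
#' Clone frequencies evolve geometrically: starting from a uniform
#' distribution over clones, each selection round in modality `m`
#' multiplies clone `i`'s frequency by its amplification factor
#' `a[i, m]` and renormalises, so after `t` rounds
#' `p_i proportional to a[i, m]^t`. Observed counts per condition are a
#' single multinomial draw of `reads_per_condition` reads from the
#' final-round frequencies.
#'
#' @param manifest truth manifest from [make_truth_manifest()].
#' @param design a [panning_design()]; conditions are simulated in
#'   design order.
#' @param reads_per_condition total reads per condition (column sums of
#'   the returned matrix equal this exactly).
#' @param seed integer RNG seed.
#' @return Integer matrix, clones x conditions.
#' @export
simulate_panning <- function(manifest, design, reads_per_condition = 1e5,
                             seed = 1L) {
  mods <- unique(design$modality)
  fac_cols <- paste0("a_", mods)
  missing <- setdiff(fac_cols, colnames(manifest))
  if (length(missing))
    stop("manifest lacks factors for modalities: ",
         paste(sub("^a_", "", missing), collapse = ", "))
  set.seed(seed)
  counts <- matrix(0L, nrow = nrow(manifest), ncol = nrow(design),
                   dimnames = list(manifest$clone_id, design$condition))
  for (j in seq_len(nrow(design))) {
    a <- manifest[[paste0("a_", design$modality[j])]]
    w <- a^design$round[j]
    if (!any(w > 0))
      stop("degenerate simulation: zero total probability in condition ",
           design$condition[j])
    counts[, j] <- stats::rmultinom(1L, size = reads_per_condition,
                                    prob = w / sum(w))[, 1L]
  }
  counts
}

#' Expected clone frequencies after panning rounds
#'
#' Deterministic limit of the geometric amplification model: the
#' expected frequency of clone `i` after `t` rounds in modality `m` is
#' `a[i, m]^t / sum_j a[j, m]^t` (uniform start).
#'
#' @param a numeric vector of per-clone amplification factors in one
#'   modality.
#' @param rounds number of selection rounds.
#' @return Numeric vector of expected frequencies (sums to 1).
#' @export
expected_frequencies <- function(a, rounds) {
  w <- a^rounds
  w / sum(w)
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Emit paired-end FASTQ reads for simulated panning counts
#'
#' Each clone's amplicon is its coding sequence flanked by 5' and 3'
#' adapters. A read pair covers the amplicon from both ends: the forward
#' read is the first `read_length` bases, the reverse read the
#' reverse-complement of the last `read_length` bases, so the pair
#' reconstructs the amplicon after adapter trimming and overlap merging.
#' Read names encode the source clone (`<clone_id>:<serial>`) so
#' processing results can be checked against the ground truth. Base
#' qualities are constant Phred `base_quality`; an optional uniform
#' substitution error rate can be applied.
#'
#' @param repertoire repertoire from [make_repertoire()].
#' @param counts clone x condition count matrix from
#'   [simulate_panning()] (clone order must match `repertoire`).
#' @param dir output directory (created if needed); one
#'   `<condition>_R1.fastq` / `_R2.fastq` pair per condition, written
#'   uncompressed.
#' @param read_length read length in nucleotides; the defaults emulate
#'   2 x 250 nt amplicon sequencing so that pairs overlap.
#' @param adapter5,adapter3 flanking adapter sequences.
#' @param error_rate per-base substitution probability (default 0).
#' @param base_quality constant Phred quality score.
#' @param seed integer RNG seed (only consumed when `error_rate > 0`).
#' @return A `data.frame` per condition with the FASTQ paths and read
#'   pair counts.
#' @export
emit_reads <- function(repertoire, counts, dir,
                       read_length = 250L,
                       adapter5 = "ACACGACGCTCTTCCGATCT",
                       adapter3 = "AGATCGGAAGAGCACACGTC",
                       error_rate = 0, base_quality = 37L, seed = 1L) {
  stopifnot(nrow(repertoire) == nrow(counts))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  amplicon <- paste0(adapter5, repertoire$nucleotide, adapter3)
  alen <- nchar(amplicon)
  if (any(read_length >= alen))
    stop("read_length must be shorter than every amplicon")
  if (any(2L * read_length - alen < 10L))
    stop("read pairs must overlap by at least 10 nt; increase read_length")
  fwd_all <- substr(amplicon, 1L, read_length)
  rev_all <- .revcomp(substring(amplicon, alen - read_length + 1L, alen))

  qual <- strrep(rawToChar(as.raw(base_quality + 33L)), read_length)
  out <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    cond <- colnames(counts)[j]
    n_per <- counts[, j]
    idx <- rep.int(seq_along(n_per), n_per)
    ids <- paste0(repertoire$clone_id[idx], ":",
                  sequence(n_per[n_per > 0L]))
    fwd <- fwd_all[idx]
    rev <- rev_all[idx]
    if (error_rate > 0 && length(idx)) {
      fwd <- .mutate_reads(fwd, error_rate)
      rev <- .mutate_reads(rev, error_rate)
    }
    f1 <- file.path(dir, paste0(cond, "_R1.fastq"))
    f2 <- file.path(dir, paste0(cond, "_R2.fastq"))
    .write_fastq(ids, fwd, qual, f1)
    .write_fastq(ids, rev, qual, f2)
    out[[j]] <- data.frame(condition = cond, r1 = f1, r2 = f2,
                           n_pairs = sum(n_per), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.write_fastq <- function(ids, seqs, qual, path) {
  sr <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(seqs),
    quality = Biostrings::BStringSet(rep_len(qual, length(seqs))),
    id = Biostrings::BStringSet(ids))
  if (file.exists(path)) file.remove(path)
  ShortRead::writeFastq(sr, path, compress = FALSE)
  invisible(path)
}

.mutate_reads <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
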