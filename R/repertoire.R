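## Repertoire processing: FASTQ pair -> merged amplicons -> in-frame
## proteins -> FR/CDR annotation -> non-redundant signature clusters.
##
## Every stage conserves reads: input = accepted + rejected, and
## rejections carry a reason code instead of being silently dropped.

#' Trim adapters and merge a set of read pairs
#'
#' Removes known 5' adapters from both mates, reverse-complements the
#' reverse mate, and merges each pair on its best suffix/prefix overlap.
#' The largest overlap of at least `min_overlap` bases whose mismatch
#' fraction does not exceed `max_mismatch_frac` is used; mismatching
#' overlap positions are resolved in favour of the higher-quality base.
#' Pairs without an acceptable overlap are rejected with reason
#' `"no_overlap"`.
#'
#' @param fwd,rev character vectors of forward / reverse read sequences.
#' @param fwd_qual,rev_qual matching Phred+33 quality strings (optional;
#'   constant high quality is assumed when absent).
#' @param adapter5 adapter expected at the 5' end of the forward read.
#' @param adapter3 adapter whose reverse complement is expected at the
#'   5' end of the reverse read.
#' @param min_overlap minimum acceptable overlap length (nt).
#' @param max_mismatch_frac maximum tolerated mismatch fraction inside
#'   the overlap.
#' @param ids optional read identifiers carried into the result.
#' @return `data.frame` with `read_id`, `merged` (NA when rejected),
#'   `status` (`"merged"`/`"rejected"`) and `reason`.
#' @export
trim_and_merge <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                           adapter5 = "ACACGACGCTCTTCCGATCT",
                           adapter3 = "AGATCGGAAGAGCACACGTC",
                           min_overlap = 10L, max_mismatch_frac = 0.1,
                           ids = NULL) {
  stopifnot(length(fwd) == length(rev))
  if (min_overlap < 1L) stop("min_overlap must be positive")
  n <- length(fwd)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_len(n))
  if (is.null(fwd_qual)) fwd_qual <- strrep("I", nchar(fwd))
  if (is.null(rev_qual)) rev_qual <- strrep("I", nchar(rev))
  rev_anchor <- .revcomp(adapter3)

  strip5 <- function(seqs, quals, adapter) {
    hit <- startsWith(seqs, adapter)
    k <- nchar(adapter)
    seqs[hit] <- substring(seqs[hit], k + 1L)
    quals[hit] <- substring(quals[hit], k + 1L)
    list(seq = seqs, qual = quals)
  }
  f <- strip5(fwd, fwd_qual, adapter5)
  r <- strip5(rev, rev_qual, rev_anchor)
  rseq <- .revcomp(r$seq)
  rqual <- vapply(strsplit(r$qual, "", fixed = TRUE),
                  function(q) paste(rev(q), collapse = ""), character(1L))

  merged <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    m <- .merge_one(f$seq[i], f$qual[i], rseq[i], rqual[i],
                    min_overlap, max_mismatch_frac)
    merged[i] <- m$seq
    reason[i] <- m$reason
  }
  data.frame(read_id = ids, merged = merged,
             status = ifelse(is.na(merged), "rejected", "merged"),
             reason = reason, stringsAsFactors = FALSE)
}

.merge_one <- function(fs, fq, rs, rq, min_overlap, max_mismatch_frac) {
  fch <- strsplit(fs, "", fixed = TRUE)[[1L]]
  rch <- strsplit(rs, "", fixed = TRUE)[[1L]]
  fqc <- utf8ToInt(fq)
  rqc <- utf8ToInt(rq)
  nf <- length(fch); nr <- length(rch)
  if (min(nf, nr) < min_overlap)
    return(list(seq = NA_character_, reason = "no_overlap"))
  for (L in seq.int(min(nf, nr), min_overlap)) {
    fi <- seq.int(nf - L + 1L, nf)
    ri <- seq_len(L)
    mis <- fch[fi] != rch[ri]
    if (sum(mis) <= max_mismatch_frac * L) {
      ov <- fch[fi]
      take_r <- mis & (rqc[ri] > fqc[fi])
      ov[take_r] <- rch[ri][take_r]
      return(list(seq = paste(c(fch[seq_len(nf - L)], ov,
                                rch[seq.int(L + 1L, length.out = nr - L)]),
                              collapse = ""),
                  reason = NA_character_))
    }
  }
  list(seq = NA_character_, reason = "no_overlap")
}

#' Detect the reading frame from a conserved FR1 label and translate
#'
#' All six frames (three offsets on both strands) of each merged
#' sequence are translated; the frame whose translation contains the
#' conserved framework-1 anchor is selected and the protein is reported
#' from the anchor start onward. Sequences whose anchor is found in no
#' frame are rejected with `"no_anchor"`, in more than one frame with
#' `"ambiguous_frame"`, and translations interrupted by a stop codon
#' with `"internal_stop"`.
#'
#' @param merged character vector of merged nucleotide sequences.
#' @param fr1_anchor conserved amino-acid label in framework 1 (>= 6
#'   residues).
#' @param ids optional sequence identifiers.
#' @return `data.frame` with `read_id`, `protein` (NA when rejected),
#'   `status`, `reason`.
#' @export
detect_frame_and_translate <- function(merged,
                                       fr1_anchor = default_fr1_anchor(),
                                       ids = NULL) {
  if (nchar(fr1_anchor) < 6L)
    stop("fr1_anchor must be at least 6 residues long")
  n <- length(merged)
  if (is.null(ids)) ids <- sprintf("seq_%06d", seq_len(n))
  frames <- .six_frame(merged)              # n x 6 character matrix
  has <- matrix(grepl(fr1_anchor, frames, fixed = TRUE), nrow = n)
  nhit <- rowSums(has)
  protein <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  reason[nhit == 0L] <- "no_anchor"
  reason[nhit > 1L] <- "ambiguous_frame"
  one <- which(nhit == 1L)
  if (length(one)) {
    sel <- frames[cbind(one, max.col(has[one, , drop = FALSE],
                                     ties.method = "first"))]
    start <- regexpr(fr1_anchor, sel, fixed = TRUE)
    body <- substring(sel, start)
    stop_at <- regexpr("*", body, fixed = TRUE)
    internal <- stop_at > 0L & stop_at < nchar(body)
    trailing <- stop_at > 0L & stop_at == nchar(body)
    body[trailing] <- substr(body[trailing], 1L,
                             nchar(body[trailing]) - 1L)
    protein[one[!internal]] <- body[!internal]
    reason[one[internal]] <- "internal_stop"
  }
  data.frame(read_id = ids, protein = protein,
             status = ifelse(is.na(protein), "rejected", "translated"),
             reason = reason, stringsAsFactors = FALSE)
}

## Translations of all six frames (3 offsets x both strands) of every
## sequence, as an n x 6 character matrix; frames too short to hold a
## codon yield "".
.six_frame <- function(nt) {
  x <- Biostrings::DNAStringSet(nt)
  strands <- list(x, Biostrings::reverseComplement(x))
  cols <- vector("list", 6L)
  k <- 0L
  for (s in strands) {
    w <- Biostrings::width(s)
    for (off in 0:2) {
      k <- k + 1L
      keep <- pmax(0L, ((w - off) %/% 3L) * 3L)
      tr <- rep("", length(s))
      ok <- keep >= 3L
      if (any(ok)) {
        sub <- Biostrings::subseq(s[ok], start = off + 1L,
                                  width = keep[ok])
        tr[ok] <- suppressWarnings(as.character(
          Biostrings::translate(sub, if.fuzzy.codon = "X")))
      }
      cols[[k]] <- tr
    }
  }
  matrix(unlist(cols), nrow = length(nt))
}

#' Annotate framework and CDR segments of a VHH protein
#'
#' Segments each protein into FR1-CDR1-FR2-CDR2-FR3-CDR3-FR4 using the
#' configured framework anchor motifs: the four motifs must occur in
#' order, FR1 at the protein start and FR4 ending at the protein end,
#' so that the segments partition the sequence. CDRs are the residues
#' between consecutive framework segments and the signature is their
#' concatenation. Proteins failing any of these constraints are
#' rejected with reason `"unannotatable"`.
#'
#' @param protein character vector of VHH protein sequences.
#' @param scheme_config named list/vector of the four framework motifs
#'   (`fr1`..`fr4`); defaults to the generator's frameworks, which
#'   approximate Chothia-style CDR delimitation for these scaffolds.
#' @param ids optional identifiers.
#' @return `data.frame` with `read_id`, `fr1`..`fr4`, `cdr1`..`cdr3`,
#'   `signature`, `status`, `reason`.
#' @export
annotate_cdrs <- function(protein, scheme_config = default_frameworks(),
                          ids = NULL) {
  need <- c("fr1", "fr2", "fr3", "fr4")
  if (!all(need %in% names(scheme_config)))
    stop("scheme_config must provide motifs fr1..fr4")
  n <- length(protein)
  if (is.null(ids)) ids <- sprintf("seq_%06d", seq_len(n))
  cols <- c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3", "fr4")
  seg <- matrix(NA_character_, n, length(cols),
                dimnames = list(NULL, cols))
  ok <- logical(n)
  for (i in seq_len(n)) {
    s <- .segment_one(protein[i], scheme_config)
    if (!is.null(s)) {
      seg[i, ] <- s
      ok[i] <- TRUE
    }
  }
  out <- data.frame(read_id = ids, seg, stringsAsFactors = FALSE)
  out$signature <- ifelse(ok, paste0(seg[, "cdr1"], seg[, "cdr2"],
                                     seg[, "cdr3"]), NA_character_)
  out$status <- ifelse(ok, "annotated", "rejected")
  out$reason <- ifelse(ok, NA_character_, "unannotatable")
  out
}

.segment_one <- function(p, cfg) {
  if (is.na(p)) return(NULL)
  pos <- integer(4L)
  len <- integer(4L)
  from <- 1L
  for (k in 1:4) {
    motif <- cfg[[paste0("fr", k)]]
    hit <- regexpr(motif, substring(p, from), fixed = TRUE)[1L]
    if (hit < 1L) return(NULL)           # missing or out-of-order anchor
    pos[k] <- from + hit - 1L
    len[k] <- nchar(motif)
    from <- pos[k] + len[k]
  }
  if (pos[1] != 1L) return(NULL)                       # FR1 must lead
  if (pos[4] + len[4] - 1L != nchar(p)) return(NULL)   # FR4 must close
  c(fr1 = substr(p, pos[1], pos[1] + len[1] - 1L),
    cdr1 = substr(p, pos[1] + len[1], pos[2] - 1L),
    fr2 = substr(p, pos[2], pos[2] + len[2] - 1L),
    cdr2 = substr(p, pos[2] + len[2], pos[3] - 1L),
    fr3 = substr(p, pos[3], pos[3] + len[3] - 1L),
    cdr3 = substr(p, pos[3] + len[3], pos[4] - 1L),
    fr4 = substr(p, pos[4], pos[4] + len[4] - 1L))
}

#' Collapse annotated records into non-redundant signature clusters
#'
#' Groups records by their exact CDR signature and tabulates
#' per-condition counts, yielding the non-redundant cluster table that
#' downstream enrichment selection consumes. Records may carry a
#' `weight` column (prior counts), making the operation idempotent:
#' collapsing an already collapsed table is a no-op.
#'
#' @param records `data.frame` with columns `signature`, `condition`
#'   and optionally `weight` (default 1 per record).
#' @return `data.frame` with `signature`, one count column per
#'   condition, and `total_raw`, ordered by `total_raw` decreasing
#'   (ties broken by signature).
#' @export
collapse_signatures <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(signature = character(0), total_raw = numeric(0)))
  stopifnot(all(c("signature", "condition") %in% names(records)))
  if (anyNA(records$signature))
    stop("all records must be annotated before collapsing")
  w <- if ("weight" %in% names(records)) records$weight else
    rep(1, nrow(records))
  tab <- stats::xtabs(w ~ signature + condition, data = records)
  m <- matrix(as.numeric(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  out <- data.frame(signature = rownames(m), m, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$total_raw <- rowSums(m)
  out[order(-out$total_raw, out$signature), , drop = FALSE]
}

#' Process per-condition FASTQ pairs into annotated records
#'
#' Runs trim/merge, frame detection/translation and CDR annotation over
#' a table of per-condition FASTQ pairs (as produced by
#' [emit_reads()]), keeping a rejection log with stage and reason for
#' every read that drops out.
#'
#' @param files `data.frame` with columns `condition`, `r1`, `r2`.
#' @param fr1_anchor conserved FR1 label for frame detection.
#' @param scheme_config framework motifs for CDR annotation.
#' @param ... passed to [trim_and_merge()].
#' @return List with `records` (annotated reads: `read_id`,
#'   `condition`, segment columns, `signature`) and `rejections`
#'   (`read_id`, `condition`, `stage`, `reason`).
#' @export
process_reads <- function(files, fr1_anchor = default_fr1_anchor(),
                          scheme_config = default_frameworks(), ...) {
  recs <- list(); rej <- list()
  for (i in seq_len(nrow(files))) {
    cond <- files$condition[i]
    r1 <- ShortRead::readFastq(files$r1[i])
    r2 <- ShortRead::readFastq(files$r2[i])
    ids <- as.character(ShortRead::id(r1))
    m <- trim_and_merge(
      fwd = as.character(ShortRead::sread(r1)),
      rev = as.character(ShortRead::sread(r2)),
      fwd_qual = as.character(methods::slot(Biostrings::quality(r1),
                                            "quality")),
      rev_qual = as.character(methods::slot(Biostrings::quality(r2),
                                            "quality")),
      ids = ids, ...)
    bad <- m$status == "rejected"
    if (any(bad))
      rej[[length(rej) + 1L]] <- data.frame(
        read_id = m$read_id[bad], condition = cond, stage = "merge",
        reason = m$reason[bad], stringsAsFactors = FALSE)
    m <- m[!bad, , drop = FALSE]

    tr <- detect_frame_and_translate(m$merged, fr1_anchor, ids = m$read_id)
    bad <- tr$status == "rejected"
    if (any(bad))
      rej[[length(rej) + 1L]] <- data.frame(
        read_id = tr$read_id[bad], condition = cond, stage = "translate",
        reason = tr$reason[bad], stringsAsFactors = FALSE)
    tr <- tr[!bad, , drop = FALSE]

    an <- annotate_cdrs(tr$protein, scheme_config, ids = tr$read_id)
    bad <- an$status == "rejected"
    if (any(bad))
      rej[[length(rej) + 1L]] <- data.frame(
        read_id = an$read_id[bad], condition = cond, stage = "annotate",
        reason = an$reason[bad], stringsAsFactors = FALSE)
    an <- an[!bad, , drop = FALSE]
    an$protein <- tr$protein[match(an$read_id, tr$read_id)]
    an$condition <- cond
    recs[[length(recs) + 1L]] <- an
  }
  empty_rej <- data.frame(read_id = character(0), condition = character(0),
                          stage = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  list(records = do.call(rbind, recs),
       rejections = if (length(rej)) do.call(rbind, rej) else empty_rej)
}
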