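## Shared fixtures built in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_signature <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

## A sequence family: point mutants of a shared core signature.
make_family <- function(core, n, n_mut = 2L) {
  vapply(seq_len(n), function(i) {
    ch <- strsplit(core, "", fixed = TRUE)[[1L]]
    pos <- sample(length(ch), n_mut)
    ch[pos] <- sample(AA20, n_mut, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1L))
}

## Three-family repertoire embedding used by the UMAP tests.
make_family_embedding <- function(seed = 99L, per_family = 50L) {
  set.seed(seed)
  cores <- vapply(1:3, function(i) random_signature(30L), character(1L))
  sigs <- unlist(lapply(cores, make_family, n = per_family))
  labels <- rep(1:3, each = per_family)
  km <- kmer_encode(sigs, k = 5L)
  list(coords = embed_signatures(km, seed = 42L),
       labels = labels, signatures = sigs)
}

## Independent brute-force re-implementation of the selection rule,
## used as an oracle: per-cluster loop, no matrix algebra shared with
## the package implementation.
brute_force_select <- function(raw, design, control_max_cpm,
                               positive_min_cpm) {
  keep <- character(0)
  for (cl in rownames(raw)) {
    hit <- FALSE
    clean <- TRUE
    for (j in seq_len(nrow(design))) {
      cpm <- 1e6 * raw[cl, design$condition[j]] / design$total_reads[j]
      if (design$role[j] == "positive" && cpm > positive_min_cpm)
        hit <- TRUE
      if (design$role[j] == "control" && cpm > control_max_cpm)
        clean <- FALSE
    }
    if (hit && clean) keep <- c(keep, cl)
  }
  keep
}

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
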