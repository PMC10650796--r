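## Synthetic VHH repertoires with a known ground truth.
##
## Clones follow the canonical single-domain architecture
## FR1-CDR1-FR2-CDR2-FR3-CDR3-FR4 with fixed framework segments (FR1
## carries the conserved "protein label" used downstream for reading
## frame detection) and random CDR content.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

#' Framework segments used by the synthetic repertoire generator
#'
#' Fixed amino-acid framework regions flanking the three CDRs. FR1
#' begins with the conserved nine-residue label returned by
#' [default_fr1_anchor()] that the processing stage uses to detect the
#' reading frame.
#'
#' @return Named character vector with elements `fr1`, `fr2`, `fr3`,
#'   `fr4`.
#' @export
default_frameworks <- function() {
  c(fr1 = "QVQLVESGGGLVQAGGSLRLSCAAS",
    fr2 = "WFRQAPGKEREFVA",
    fr3 = "RFTISRDNAKNTVYLQMNSLKPEDTAVYYC",
    fr4 = "WGQGTQVTVSS")
}

#' Conserved FR1 anchor label
#'
#' The nine-residue prefix of the default FR1 segment; a conserved
#' protein label expected in framework 1 of every clone, used to select
#' the translation frame of merged amplicons.
#' @return A length-one character string.
#' @export
default_fr1_anchor <- function() substr(default_frameworks()[["fr1"]], 1L, 9L)

## Uniform random back-translation: one codon drawn per residue.
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.backtranslate <- function(protein, codons = .codon_table()) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1L)), collapse = "")
}

.random_peptide <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic VHH repertoire
#'
#' Creates `n_clones` clone records sharing fixed framework regions and
#' carrying random CDRs whose lengths are drawn uniformly from the
#' configured ranges. Each protein is back-translated with uniformly
#' sampled synonymous codons so that the nucleotide sequence translates
#' in frame to the protein.
#'
#' @param n_clones number of clones (>= 1).
#' @param cdr_length_ranges named list with elements `cdr1`, `cdr2`,
#'   `cdr3`, each `c(min, max)` amino-acid lengths.
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   repertoires.
#' @param frameworks framework segments, see [default_frameworks()].
#' @return A `data.frame` with one row per clone: `clone_id`,
#'   `nucleotide`, `protein`, `fr1`..`fr4`, `cdr1`..`cdr3` and
#'   `signature` (the concatenated CDRs, the clustering key).
#' @examples
#' rep1 <- make_repertoire(3, seed = 7)
#' rep1$signature
#' @export
make_repertoire <- function(n_clones,
                            cdr_length_ranges = list(cdr1 = c(5L, 8L),
                                                     cdr2 = c(6L, 10L),
                                                     cdr3 = c(8L, 18L)),
                            seed = 1L,
                            frameworks = default_frameworks()) {
  if (n_clones < 1) stop("n_clones must be >= 1")
  for (nm in c("cdr1", "cdr2", "cdr3")) {
    r <- cdr_length_ranges[[nm]]
    if (is.null(r) || length(r) != 2L || any(r < 1) || r[1] > r[2])
      stop("invalid length range for ", nm,
           ": need c(min, max) with 1 <= min <= max")
  }
  set.seed(seed)
  codons <- .codon_table()
  lens <- lapply(cdr_length_ranges[c("cdr1", "cdr2", "cdr3")], function(r)
    sample(seq.int(r[1], r[2]), n_clones, replace = TRUE))
  rows <- lapply(seq_len(n_clones), function(i) {
    cdrs <- c(.random_peptide(lens$cdr1[i]),
              .random_peptide(lens$cdr2[i]),
              .random_peptide(lens$cdr3[i]))
    protein <- paste0(frameworks[["fr1"]], cdrs[1], frameworks[["fr2"]],
                      cdrs[2], frameworks[["fr3"]], cdrs[3],
                      frameworks[["fr4"]])
    data.frame(clone_id = sprintf("clone_%04d", i),
               nucleotide = .backtranslate(protein, codons),
               protein = protein,
               fr1 = frameworks[["fr1"]], cdr1 = cdrs[1],
               fr2 = frameworks[["fr2"]], cdr2 = cdrs[2],
               fr3 = frameworks[["fr3"]], cdr3 = cdrs[3],
               fr4 = frameworks[["fr4"]],
               signature = paste0(cdrs[1], cdrs[2], cdrs[3]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a ground-truth binding manifest for a repertoire
#'
#' Designates target binders (amplified round over round in one
#' target-positive modality) and background binders (amplified in every
#' negative-control modality, emulating matrix/plastic binders), and
#' assigns every clone a per-modality amplification factor. Non-binding
#' clone/modality pairs get factor 1 (carried along passively).
#'
#' @param repertoire output of [make_repertoire()].
#' @param design a [panning_design()].
#' @param n_target,n_background numbers of spiked target and background
#'   binders.
#' @param target_factor per-round amplification of a target binder in
#'   its assigned positive modality (> 1).
#' @param background_factor per-round amplification of a background
#'   binder in all control modalities (> 1).
#' @param seed integer RNG seed.
#' @return A `data.frame` (the truth manifest): `clone_id`,
#'   `protein_seq`, `signature`, `is_target_binder`,
#'   `is_background_binder`, `target_modality`, `seed`, and one factor
#'   column `a_<modality>` per modality in the design.
#' @export
make_truth_manifest <- function(repertoire, design,
                                n_target = 20L, n_background = 20L,
                                target_factor = 4, background_factor = 4,
                                seed = 1L) {
  n <- nrow(repertoire)
  if (n_target + n_background > n)
    stop("more binders requested than clones available")
  if (target_factor <= 1 || background_factor <= 1)
    stop("amplification factors of spiked binders must be > 1")
  set.seed(seed)
  mods <- unique(design$modality)
  pos_mods <- unique(design$modality[design$role == "positive"])
  ctrl_mods <- unique(design$modality[design$role == "control"])
  picks <- sample.int(n, n_target + n_background)
  target_idx <- picks[seq_len(n_target)]
  bg_idx <- picks[n_target + seq_len(n_background)]

  fac <- matrix(1, nrow = n, ncol = length(mods),
                dimnames = list(repertoire$clone_id, mods))
  assigned <- rep(NA_character_, n)
  assigned[target_idx] <- rep_len(pos_mods, n_target)
  for (i in target_idx) fac[i, assigned[i]] <- target_factor
  for (i in bg_idx) fac[i, ctrl_mods] <- background_factor

  manifest <- data.frame(
    clone_id = repertoire$clone_id,
    protein_seq = repertoire$protein,
    signature = repertoire$signature,
    is_target_binder = seq_len(n) %in% target_idx,
    is_background_binder = seq_len(n) %in% bg_idx,
    target_modality = assigned,
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  colnames(fac) <- paste0("a_", mods)
  cbind(manifest, as.data.frame(fac))
}

#' Write / read a truth manifest as TSV
#'
#' The manifest round-trips losslessly: `read_manifest(write_manifest(m,
#' f))` reproduces `m` exactly (factors are written with full
#' precision).
#'
#' @param manifest a manifest from [make_truth_manifest()].
#' @param path TSV file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  m$is_target_binder <- as.logical(m$is_target_binder)
  m$is_background_binder <- as.logical(m$is_background_binder)
  m$target_modality <- as.character(m$target_modality)
  m$target_modality[m$target_modality == "NA"] <- NA_character_
  m
}
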