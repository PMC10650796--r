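#' Declare a panning design
#'
#' A panning design lists the conditions of a multiplexed phage-display
#' experiment. Each condition is one physical presentation of the target
#' (a "modality": whole cells, membranes, proteoliposomes, ectodomain
#' fusion, peptide, ...) sequenced after a given number of selection
#' rounds, and plays either a target-positive or a negative-control role.
#'
#' @param condition character, unique condition identifiers (one NGS
#'   library each).
#' @param modality character, modality name shared by conditions that
#'   present the same surface (a clone's binding factor is indexed by
#'   modality, not by round).
#' @param round integer, number of panning rounds carried out before
#'   sequencing (typically 2 or 3).
#' @param role `"positive"` or `"control"`.
#' @param total_reads optional numeric, total read count per condition
#'   (used for counts-per-million normalisation).
#' @return A `data.frame` of class `panning_design` with one row per
#'   condition.
#' @examples
#' panning_design(
#'   condition = c("ecd_R3", "mbp_ctrl"),
#'   modality = c("ecd_fshr", "mbp_ctrl"),
#'   round = c(3L, 3L),
#'   role = c("positive", "control")
#' )
#' @export
panning_design <- function(condition, modality, round, role,
                           total_reads = NA_real_) {
  role <- match.arg(role, c("positive", "control"), several.ok = TRUE)
  if (anyDuplicated(condition))
    stop("condition identifiers must be unique")
  if (any(round < 1))
    stop("rounds must be >= 1")
  d <- data.frame(
    condition = as.character(condition),
    modality = as.character(modality),
    round = as.integer(round),
    role = rep_len(role, length(condition)),
    total_reads = rep_len(as.numeric(total_reads), length(condition)),
    stringsAsFactors = FALSE
  )
  if (!any(d$role == "positive") || !any(d$role == "control"))
    stop("a panning design needs at least one positive and one control condition")
  class(d) <- c("panning_design", class(d))
  d
}

#' Default 12-condition multiplexed panning design
#'
#' Six modality families -- proteoliposomes, whole cells, maltose-binding
#' protein (MBP) ectodomain fusion, receptor N-terminal peptide, isolated
#' ectodomain, and cell membranes -- with negative controls for the
#' proteoliposome, cell, MBP and membrane families, sequenced after two
#' (R2) or three (R3) rounds of selection. This mirrors the condition
#' layout of a multiplexed anti-receptor VHH selection campaign.
#'
#' @param total_reads reads per condition used for CPM normalisation
#'   (recycled across conditions).
#' @return A [panning_design()].
#' @export
default_panning_design <- function(total_reads = 1e5) {
  panning_design(
    condition = c("proteoliposomes_ctrl", "proteoliposomes_fshr_R3",
                  "cells_ctrl", "cells_fshr_R2", "cells_fshr_R3",
                  "mbp_ctrl", "mbp_fshr_R2", "mbp_fshr_R3",
                  "peptide_fshr_R2", "ecd_fshr_R3",
                  "membranes_ctrl", "membranes_fshr_R3"),
    modality = c("proteoliposomes_ctrl", "proteoliposomes_fshr",
                 "cells_ctrl", "cells_fshr", "cells_fshr",
                 "mbp_ctrl", "mbp_fshr", "mbp_fshr",
                 "peptide_fshr", "ecd_fshr",
                 "membranes_ctrl", "membranes_fshr"),
    round = c(3L, 3L, 3L, 2L, 3L, 3L, 2L, 3L, 2L, 3L, 3L, 3L),
    role = c("control", "positive", "control", "positive", "positive",
             "control", "positive", "positive", "positive", "positive",
             "control", "positive"),
    total_reads = total_reads
  )
}

#' Load the packaged candidate-cluster count fixture
#'
#' Reads the packaged per-million-normalised cluster count table of a
#' 12-condition multiplexed selection (34 candidate clusters, the
#' largest of which is PRC1) together with its matching panning design.
#' Counts in this table are already normalised per million reads per
#' condition, so the design declares one million reads per condition,
#' making raw counts and CPM coincide.
#'
#' @return A list with elements `counts` (cluster x condition numeric
#'   matrix), `total` (the printed per-cluster raw totals) and `design`
#'   (a [panning_design()]).
#' @examples
#' fx <- load_table1()
#' sum(fx$counts["PRC1", ])
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.tsv", package = "vhhscreen",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, !(names(tab) %in% c("cluster", "total"))])
  rownames(counts) <- tab$cluster
  storage.mode(counts) <- "numeric"
  design <- default_panning_design(total_reads = 1e6)
  stopifnot(identical(colnames(counts), design$condition))
  list(counts = counts,
       total = stats::setNames(tab$total, tab$cluster),
       design = design)
}
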