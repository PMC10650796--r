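## Counts-per-million normalisation and the multiplexed selection rule:
## a cluster is a candidate when it is present in at least one
## target-positive condition and absent from (or below threshold in)
## every negative-control condition.

#' Normalise a cluster count matrix to counts per million
#'
#' `cpm[c, k] = 1e6 * raw[c, k] / total_reads[k]`. Columns with a zero
#' total and no counts normalise to zero without error; a column whose
#' counts exceed its declared total is an integrity error.
#'
#' @param raw cluster x condition count matrix (column names must match
#'   the design's conditions).
#' @param design a [panning_design()] carrying `total_reads`.
#' @return Object of class `vhh_counts`: list with `raw`, `cpm`,
#'   `design`.
#' @export
normalize_cpm <- function(raw, design) {
  raw <- as.matrix(raw)
  if (!identical(colnames(raw), design$condition))
    stop("count matrix columns must match the design's conditions")
  totals <- design$total_reads
  csums <- colSums(raw)
  if (any(is.na(totals) & csums > 0))
    stop("total_reads missing for a condition that has counts")
  if (any(!is.na(totals) & csums > totals))
    stop("column counts exceed the declared condition total")
  scale <- ifelse(is.na(totals) | totals == 0, 0, 1e6 / totals)
  cpm <- sweep(raw, 2L, scale, `*`)
  structure(list(raw = raw, cpm = cpm, design = design),
            class = "vhh_counts")
}

#' Apply the multiplexed enrichment selection rule
#'
#' A cluster is selected iff its CPM exceeds `positive_min_cpm` in at
#' least one target-positive condition AND is at or below
#' `control_max_cpm` in every negative-control condition. The default
#' `control_max_cpm = 0` is the strict "absent from all controls"
#' reading; a nonzero threshold accommodates sequencing background.
#' Selected clusters are ranked by total raw count (decreasing), ties
#' broken by cluster name.
#'
#' @param counts a `vhh_counts` object from [normalize_cpm()].
#' @param control_max_cpm maximum tolerated CPM in any control
#'   condition (>= 0).
#' @param positive_min_cpm CPM that must be strictly exceeded in at
#'   least one positive condition (> 0).
#' @return Object of class `vhh_selection`: `data.frame` of selected
#'   clusters (`cluster`, `n_positive_hits`, `max_positive_cpm`,
#'   `total_raw`), ranked; attributes keep the thresholds and the full
#'   `vhh_counts`.
#' @export
select_candidates <- function(counts, control_max_cpm = 0,
                              positive_min_cpm = 1) {
  stopifnot(inherits(counts, "vhh_counts"))
  if (control_max_cpm < 0 || positive_min_cpm <= 0)
    stop("thresholds must satisfy control_max_cpm >= 0, positive_min_cpm > 0")
  design <- counts$design
  cpm <- counts$cpm
  pos <- cpm[, design$role == "positive", drop = FALSE]
  ctl <- cpm[, design$role == "control", drop = FALSE]
  hit_pos <- rowSums(pos > positive_min_cpm) >= 1L
  clean_ctl <- rowSums(ctl > control_max_cpm) == 0L
  keep <- hit_pos & clean_ctl
  total_raw <- rowSums(counts$raw)
  sel <- data.frame(
    cluster = rownames(cpm)[keep],
    n_positive_hits = rowSums(pos > positive_min_cpm)[keep],
    max_positive_cpm = apply(pos, 1L, max)[keep],
    total_raw = total_raw[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
  sel <- sel[order(-sel$total_raw, sel$cluster), , drop = FALSE]
  rownames(sel) <- NULL
  structure(sel, class = c("vhh_selection", "data.frame"),
            control_max_cpm = control_max_cpm,
            positive_min_cpm = positive_min_cpm,
            counts = counts)
}

#' Tabular report of a selection result
#'
#' One row per selected cluster, one CPM column per condition, plus the
#' raw total; the layout of a selected-clusters summary table. The
#' report round-trips losslessly through TSV via [write_report()] /
#' [read_report()].
#'
#' @param selection a `vhh_selection` from [select_candidates()].
#' @return `data.frame` with `cluster`, per-condition CPM columns and
#'   `total_raw`.
#' @export
cluster_report <- function(selection) {
  stopifnot(inherits(selection, "vhh_selection"))
  if (nrow(selection) == 0L) stop("selection is empty")
  counts <- attr(selection, "counts")
  cpm <- counts$cpm[selection$cluster, , drop = FALSE]
  data.frame(cluster = selection$cluster, cpm,
             total_raw = selection$total_raw,
             check.names = FALSE, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @rdname cluster_report
#' @param report a report `data.frame`.
#' @param path TSV path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname cluster_report
#' @export
read_report <- function(path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
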