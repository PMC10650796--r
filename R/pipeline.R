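## End-to-end orchestration: synthetic generation -> read processing ->
## enrichment selection -> embedding, driven by one (YAML) config, with
## a content-hashed run manifest for reproducibility.

#' Default pipeline configuration
#'
#' @param seed master seed for all stages.
#' @param outdir output directory for all stage artefacts.
#' @return Named list understood by [run_pipeline()]. Fields:
#'   `seed`, `outdir`, `stages` (subset of `synth`, `repertoire`,
#'   `select`, `embed`, run in this order), `n_clones`, `n_target`,
#'   `n_background`, `target_factor`, `background_factor`,
#'   `reads_per_condition`, `emit_fastq` (write and re-process FASTQ
#'   pairs; when `FALSE` the signature clusters are tabulated directly
#'   from the simulated counts), `read_length`, `control_max_cpm`,
#'   `positive_min_cpm`, `umap_k`, `umap_neighbors`.
#' @export
default_pipeline_config <- function(seed = 1L, outdir = tempfile("vhhrun")) {
  list(seed = as.integer(seed), outdir = outdir,
       stages = c("synth", "repertoire", "select", "embed"),
       n_clones = 300L, n_target = 20L, n_background = 20L,
       target_factor = 4, background_factor = 4,
       reads_per_condition = 1e5, emit_fastq = FALSE,
       read_length = 250L,
       control_max_cpm = 1000, positive_min_cpm = 5000,
       umap_k = 5L, umap_neighbors = 15L)
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(base, config)
}

.stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline halted in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the selection pipeline end-to-end
#'
#' Executes the enabled stages sequentially, writing every artefact
#' (manifest, count matrices, cluster table, selection report,
#' embedding coordinates) as TSV under `config$outdir`, and finishes
#' with `run_manifest.json` recording the package version, seed, the
#' full configuration and an MD5 content hash of every output file.
#' Deterministic given the seed; a failing stage halts the run with the
#' stage name and reason. Stages later in the order can be re-run on an
#' existing output directory as long as the artefacts they consume are
#' present.
#'
#' @param config configuration list (see [default_pipeline_config()])
#'   or path to a YAML file with the same fields.
#' @return Invisibly, a list with the stage results and the manifest
#'   path.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- .load_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config.yaml"))
  design <- default_panning_design(total_reads = cfg$reads_per_condition)
  res <- list(config = cfg, design = design)

  if ("synth" %in% cfg$stages) {
    res$repertoire <- .stage_fail("synth", make_repertoire(
      cfg$n_clones, seed = cfg$seed))
    res$manifest <- .stage_fail("synth", make_truth_manifest(
      res$repertoire, design, n_target = cfg$n_target,
      n_background = cfg$n_background,
      target_factor = cfg$target_factor,
      background_factor = cfg$background_factor, seed = cfg$seed))
    res$counts <- .stage_fail("synth", simulate_panning(
      res$manifest, design, reads_per_condition = cfg$reads_per_condition,
      seed = cfg$seed))
    write_manifest(res$manifest, file.path(cfg$outdir, "manifest.tsv"))
    utils::write.table(data.frame(clone_id = rownames(res$counts),
                                  res$counts, check.names = FALSE),
                       file.path(cfg$outdir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (cfg$emit_fastq)
      res$fastq <- .stage_fail("synth", emit_reads(
        res$repertoire, res$counts, file.path(cfg$outdir, "fastq"),
        read_length = cfg$read_length, seed = cfg$seed))
  }

  if ("repertoire" %in% cfg$stages && is.null(res$manifest) &&
      !cfg$emit_fastq) {
    res$manifest <- .stage_fail("repertoire", read_manifest(
      file.path(cfg$outdir, "manifest.tsv")))
    ctab <- .stage_fail("repertoire", utils::read.delim(
      file.path(cfg$outdir, "counts.tsv"), check.names = FALSE))
    res$counts <- as.matrix(ctab[, -1, drop = FALSE])
    rownames(res$counts) <- ctab$clone_id
  }

  if ("repertoire" %in% cfg$stages) {
    res$clusters <- .stage_fail("repertoire", {
      if (cfg$emit_fastq) {
        pr <- process_reads(res$fastq)
        utils::write.table(pr$rejections,
                           file.path(cfg$outdir, "rejections.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        collapse_signatures(pr$records)
      } else {
        # signature-level tabulation straight from the simulated counts
        long <- data.frame(
          signature = rep(res$manifest$signature, ncol(res$counts)),
          condition = rep(colnames(res$counts), each = nrow(res$counts)),
          weight = as.vector(res$counts))
        collapse_signatures(long[long$weight > 0, ])
      }
    })
    utils::write.table(res$clusters, file.path(cfg$outdir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("select" %in% cfg$stages) {
    res$selection <- .stage_fail("select", {
      cl <- res$clusters
      if (is.null(cl))
        cl <- utils::read.delim(file.path(cfg$outdir, "clusters.tsv"),
                                check.names = FALSE)
      for (cond in setdiff(design$condition, names(cl))) cl[[cond]] <- 0
      m <- as.matrix(cl[, design$condition, drop = FALSE])
      rownames(m) <- cl$signature
      select_candidates(normalize_cpm(m, design),
                        control_max_cpm = cfg$control_max_cpm,
                        positive_min_cpm = cfg$positive_min_cpm)
    })
    if (nrow(res$selection) > 0L) {
      write_report(cluster_report(res$selection),
                   file.path(cfg$outdir, "selection.tsv"))
    } else {
      write_report(data.frame(cluster = character(0)),
                   file.path(cfg$outdir, "selection.tsv"))
    }
  }

  if ("embed" %in% cfg$stages) {
    res$embedding <- .stage_fail("embed", {
      cl <- res$clusters
      if (is.null(cl))
        cl <- utils::read.delim(file.path(cfg$outdir, "clusters.tsv"),
                                check.names = FALSE)
      km <- kmer_encode(cl$signature, k = cfg$umap_k)
      embed_signatures(km, n_neighbors = cfg$umap_neighbors,
                       seed = cfg$seed)
    })
    utils::write.table(
      data.frame(signature = rownames(res$embedding), res$embedding),
      file.path(cfg$outdir, "embedding.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- sort(setdiff(list.files(cfg$outdir, recursive = TRUE),
                        "run_manifest.json"))
  manifest <- list(
    package = "vhhscreen",
    version = as.character(utils::packageVersion("vhhscreen")),
    seed = cfg$seed,
    stages = cfg$stages,
    config = cfg,
    files = as.list(tools::md5sum(file.path(cfg$outdir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest,
                       file.path(cfg$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest_path <- file.path(cfg$outdir, "run_manifest.json")
  invisible(res)
}
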