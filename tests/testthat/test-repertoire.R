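make_processed_run <- function(n_clones = 40L, pairs_per_clone = 2L,
                               seed = 21L) {
  rep1 <- make_repertoire(n_clones, seed = seed)
  counts <- matrix(as.integer(pairs_per_clone), nrow = n_clones, ncol = 1,
                   dimnames = list(rep1$clone_id, "condA"))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  files <- emit_reads(rep1, counts, dir, seed = seed)
  list(repertoire = rep1, files = files, counts = counts)
}

test_that("error-free pairs merge back to their source amplicon", {
  run <- make_processed_run(n_clones = 30L)
  r1 <- ShortRead::readFastq(run$files$r1)
  r2 <- ShortRead::readFastq(run$files$r2)
  m <- trim_and_merge(as.character(ShortRead::sread(r1)),
                      as.character(ShortRead::sread(r2)),
                      ids = sub(":.*$", "",
                                as.character(ShortRead::id(r1))))
  expect_true(all(m$status == "merged"))
  src <- run$repertoire$nucleotide[match(m$read_id,
                                         run$repertoire$clone_id)]
  expect_identical(m$merged, src)
})

test_that("non-overlapping pairs are rejected with a reason code", {
  # two reads from unrelated sequences cannot overlap
  set.seed(1)
  a <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  m <- trim_and_merge(a, .revcomp_chr(b), adapter5 = "GGGGG",
                      adapter3 = "CCCCC")
  expect_equal(m$status, "rejected")
  expect_equal(m$reason, "no_overlap")
})

test_that("overlap consensus takes the higher-quality base", {
  left <- "ACGTACGTACGTACGT"
  right <- "ACGTACGTACGTACGTTTTT"
  # mutate one overlap position on the forward read, give it low quality
  fwd <- sub("^ACGTA", "ACGTT", left)
  m <- trim_and_merge(fwd, .revcomp_chr(right),
                      fwd_qual = strrep("#", nchar(fwd)),
                      rev_qual = strrep("I", nchar(right)),
                      adapter5 = "GGGGGGGG", adapter3 = "GGGGGGGG",
                      min_overlap = 10)
  expect_equal(m$status, "merged")
  expect_equal(m$merged, right)
})

test_that("frame detection finds the anchored frame on either strand", {
  rep1 <- make_repertoire(5, seed = 31)
  tr <- detect_frame_and_translate(rep1$nucleotide)
  expect_true(all(tr$status == "translated"))
  expect_identical(tr$protein, rep1$protein)

  # reverse strand with a frame shift
  shifted <- paste0("GG", .revcomp_chr(rep1$nucleotide[1]))
  tr2 <- detect_frame_and_translate(shifted)
  expect_equal(tr2$status, "translated")
  expect_equal(tr2$protein, rep1$protein[1])

  # random sequence lacks the anchor
  set.seed(2)
  junk <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  tr3 <- detect_frame_and_translate(junk)
  expect_equal(tr3$reason, "no_anchor")
})

test_that("an internal stop codon is rejected", {
  rep1 <- make_repertoire(1, seed = 41)
  nt <- rep1$nucleotide
  # TAA inserted mid-sequence, in frame, after the anchor region
  pos <- 34 * 3
  broken <- paste0(substr(nt, 1, pos), "TAA",
                   substr(nt, pos + 1, nchar(nt)))
  tr <- detect_frame_and_translate(broken)
  expect_equal(tr$reason, "internal_stop")
})

test_that("CDR annotation reproduces the generator's boundaries", {
  rep1 <- make_repertoire(500, seed = 51)
  ann <- annotate_cdrs(rep1$protein)
  expect_true(all(ann$status == "annotated"))
  for (col in c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3", "fr4"))
    expect_identical(ann[[col]], rep1[[col]])
  expect_identical(ann$signature, rep1$signature)
})

test_that("proteins missing an anchor are unannotatable", {
  rep1 <- make_repertoire(2, seed = 61)
  no_fr4 <- substr(rep1$protein[1], 1, nchar(rep1$protein[1]) - 11)
  ann <- annotate_cdrs(no_fr4)
  expect_equal(ann$reason, "unannotatable")
  # out-of-order anchors
  fw <- default_frameworks()
  scrambled <- paste0(fw[["fr2"]], "AAAA", fw[["fr1"]], "CCCC",
                      fw[["fr3"]], "DDDD", fw[["fr4"]])
  expect_equal(annotate_cdrs(scrambled)$reason, "unannotatable")
})

test_that("collapse groups by exact signature and conserves counts", {
  recs <- data.frame(
    signature = c("AAA", "BBB", "AAA"),
    condition = c("c1", "c1", "c1"))
  cl <- collapse_signatures(recs)
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$total_raw), c(1, 2))
  expect_equal(sum(cl$total_raw), nrow(recs))

  empty <- collapse_signatures(recs[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("collapsing a collapsed table is a no-op", {
  set.seed(3)
  recs <- data.frame(
    signature = sample(c("AAA", "BBB", "CCC"), 50, TRUE),
    condition = sample(c("c1", "c2"), 50, TRUE))
  once <- collapse_signatures(recs)
  long <- do.call(rbind, lapply(setdiff(names(once),
                                        c("signature", "total_raw")),
                                function(cond)
    data.frame(signature = once$signature, condition = cond,
               weight = once[[cond]])))
  twice <- collapse_signatures(long[long$weight > 0, ])
  expect_equal(twice, once, ignore_attr = TRUE)
})

test_that("zero-error synthetic reads pass every stage with 0 rejections", {
  run <- make_processed_run(n_clones = 40L, pairs_per_clone = 3L)
  pr <- process_reads(run$files)
  expect_equal(nrow(pr$rejections), 0L)
  expect_equal(nrow(pr$records), sum(run$counts))

  # exact manifest round-trip, read by read
  src <- sub(":.*$", "", pr$records$read_id)
  truth <- run$repertoire[match(src, run$repertoire$clone_id), ]
  expect_identical(pr$records$signature, truth$signature)
  expect_identical(pr$records$protein, truth$protein)

  # cluster count equals distinct observed signatures
  cl <- collapse_signatures(pr$records)
  expect_equal(nrow(cl), length(unique(truth$signature)))
  expect_equal(sum(cl$total_raw), nrow(pr$records))
})

test_that("rejected reads are logged, not dropped: counts reconcile", {
  run <- make_processed_run(n_clones = 15L, pairs_per_clone = 2L)
  r1 <- ShortRead::readFastq(run$files$r1)
  r2 <- ShortRead::readFastq(run$files$r2)
  fwd <- as.character(ShortRead::sread(r1))
  rev <- as.character(ShortRead::sread(r2))
  # corrupt a third of the reverse mates so their overlap is destroyed
  bad <- seq_len(10)
  set.seed(4)
  rev[bad] <- vapply(bad, function(i)
    paste(sample(c("A", "C", "G", "T"), nchar(rev[i]), TRUE),
          collapse = ""), character(1))
  m <- trim_and_merge(fwd, rev)
  expect_equal(sum(m$status == "merged") + sum(m$status == "rejected"),
               length(fwd))
  expect_true(all(m$reason[m$status == "rejected"] == "no_overlap"))
  expect_gte(sum(m$status == "rejected"), length(bad))
})
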