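# tRNA pool quantification: name parsing, occupancy, relative expression,
# aggregation, composition, diversity, and identical-sequence collapsing.

test_that("gene name parsing handles the gtRNAdb dialect and tRX entries", {
  p <- parse_trna_gene_name("tRNA-Ile-TAT-2-1")
  expect_equal(p$isotype, "Ile")
  expect_equal(p$anticodon, "TAT")
  expect_equal(p$transcript_group, 2L)
  expect_equal(p$copy, 1L)
  expect_false(p$is_trx)

  p <- parse_trna_gene_name("tRNA-Arg-TCT-4-1")
  expect_equal(unlist(p[, c("isotype", "anticodon")], use.names = FALSE),
               c("Arg", "TCT"))

  # en-dash dialect, no-prefix dialect
  expect_equal(parse_trna_gene_name("tRNA-Ile-TAT-2–1")$copy, 1L)
  expect_equal(parse_trna_gene_name("Gly-GCC-1-2")$transcript_group, 1L)

  # tRX flagged for exclusion, anticodon may contain N
  p <- parse_trna_gene_name("tRX-NNN-1-1")
  expect_true(p$is_trx)
  expect_equal(p$anticodon, "NNN")

  expect_error(parse_trna_gene_name("not-a-trna"), "not-a-trna")
  expect_error(parse_trna_gene_name(""), "empty")
})

test_that("occupancy requires strictly more than min_reads in every replicate", {
  counts <- matrix(c(3, 5,
                     2, 100,
                     0, 0,
                     7, 3),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), c("A_rep1", "A_rep2")))
  sheet <- data.frame(sample = colnames(counts), cell_type = "A",
                      replicate = 1:2)
  occ <- classify_expressed(counts, sheet)
  expect_equal(unname(occ[, "A"]), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unname(attr(occ, "any_cell_type")),
               c(TRUE, FALSE, FALSE, TRUE))

  # single-replicate cell type degenerates with a warning
  sheet1 <- data.frame(sample = "A_rep1", cell_type = "solo", replicate = 1)
  expect_warning(occ1 <- classify_expressed(counts[, 1, drop = FALSE], sheet1),
                 "single replicate")
  expect_equal(unname(occ1[, "solo"]), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("occupancy is monotone in counts", {
  set.seed(77)
  for (i in 1:20) {
    counts <- matrix(rpois(12, 4), nrow = 3,
                     dimnames = list(paste0("g", 1:3),
                                     c("X_r1", "X_r2", "Y_r1", "Y_r2")))
    sheet <- data.frame(sample = colnames(counts),
                        cell_type = rep(c("X", "Y"), each = 2),
                        replicate = rep(1:2, 2))
    before <- classify_expressed(counts, sheet)
    bumped <- counts
    bumped[sample(length(bumped), 4)] <- bumped[sample(length(bumped), 4)] + 5
    after <- classify_expressed(bumped, sheet)
    expect_true(all(after[before]))  # raising counts never turns TRUE off
  }
})

test_that("relative expression normalizes per sample and averages replicates", {
  toy <- toy_counts()
  expr <- relative_expression(toy$counts, toy$sheet, toy_annotation(),
                              exclude_trx = TRUE)
  expect_equal(colSums(expr$values), rep(1, 4), ignore_attr = TRUE)
  # hand-computed: N_rep1 {50,50,3}/103
  expect_equal(unname(expr$values[, "N_rep1"]), c(50, 50, 3) / 103)
  # cell-type value is the mean of replicate fractions
  expect_equal(unname(expr$by_cell_type[, "N"]),
               rowMeans(cbind(c(50, 50, 3) / 103, c(40, 60, 5) / 105)),
               ignore_attr = TRUE)
  # pooled-count alternative pools raw reads
  expr_p <- relative_expression(toy$counts, toy$sheet, toy_annotation(),
                                cell_type_stat = "pooled_counts")
  expect_equal(unname(expr_p$by_cell_type[, "N"]),
               c(90, 110, 8) / 208)
})

test_that("tRX genes are excluded before normalization with an audit trail", {
  toy <- toy_counts()
  counts <- rbind(toy$counts,
                  "tRX-NNN-1-1" = c(10, 10, 10, 10))
  expr <- relative_expression(counts, toy$sheet)
  expect_equal(expr$excluded, "tRX-NNN-1-1")
  expect_false("tRX-NNN-1-1" %in% rownames(expr$values))
  expect_equal(colSums(expr$values), rep(1, 4), ignore_attr = TRUE)
})

test_that("an all-zero sample is an error naming the sample", {
  toy <- toy_counts()
  counts <- toy$counts
  counts[, "G_rep2"] <- 0
  expect_error(relative_expression(counts, toy$sheet), "G_rep2")
})

test_that("aggregation sums member genes and conserves totals", {
  toy <- toy_counts()
  expr <- relative_expression(toy$counts, toy$sheet, toy_annotation())
  iso <- aggregate_expression(expr, toy_annotation(), "isoacceptor")
  expect_equal(rownames(iso$values), c("Arg-TCT", "Ile-TAT"))
  expect_equal(unname(iso$values["Ile-TAT", "N_rep1"]), 100 / 103)
  # conservation: isoacceptor totals equal gene totals per sample
  expect_equal(colSums(iso$values), colSums(expr$values))
  # isotype rolls both Ile-TAT genes and any other Ile families together
  ityp <- aggregate_expression(expr, toy_annotation(), "isotype")
  expect_equal(unname(ityp$values["Ile", "G_rep1"]), 100 / 100)
  # aggregate is linear: normalizing then aggregating == aggregating counts
  agg_counts <- collapse_identical(toy$counts, toy_annotation())
  expr2 <- relative_expression(agg_counts, toy$sheet, annotation = NULL,
                               exclude_trx = FALSE)
  tg <- aggregate_expression(expr, toy_annotation(), "transcript_group")
  expect_equal(tg$values, expr2$values[rownames(tg$values), ])
})

test_that("within-family composition reports fractions and undefined families", {
  toy <- toy_counts()
  expr <- relative_expression(toy$counts, toy$sheet, toy_annotation())
  comp <- family_composition(expr, toy_annotation())
  # single-gene family has fraction 1
  expect_equal(unname(comp["tRNA-Arg-TCT-4-1", "N"]), 1)
  # two-gene family fractions sum to 1
  expect_equal(sum(comp[c("tRNA-Ile-TAT-2-1", "tRNA-Ile-TAT-2-2"), "G"]), 1)
  # a zero-total family is undefined (NA), not zero
  counts0 <- rbind(toy$counts, "tRNA-Gly-GCC-1-1" = c(0, 0, 0, 0))
  ann0 <- toy_annotation()
  extra <- data.frame(gene_name = "tRNA-Gly-GCC-1-1", isotype = "Gly",
                      anticodon = "GCC", transcript_group = 1L, copy = 1L,
                      identical_group_id = "Gly-GCC-1", is_trx = FALSE,
                      is_high_confidence = TRUE, chrom = "chr2",
                      start = 5L, end = 77L, strand = "+")
  ann0 <- rbind(as.data.frame(ann0), extra)
  class(ann0) <- c("trna_annotation", "data.frame")
  expr0 <- relative_expression(counts0, toy$sheet, ann0)
  comp0 <- family_composition(expr0, ann0)
  expect_true(is.na(comp0["tRNA-Gly-GCC-1-1", "N"]))
  expect_true("Gly-GCC" %in% attr(comp0, "undefined_families")[["N"]])
})

test_that("diversity counts strict >5% contributors", {
  comp <- matrix(c(0.90, 0.05, 0.05,
                   0.25, 0.25, 0.25),
                 ncol = 2,
                 dimnames = list(paste0("g", 1:3), c("ct1", "ct2")))
  comp <- cbind(comp, ct3 = c(0.52, 0.48, NA))
  attr(comp, "family") <- c("F1", "F1", "F1")
  div <- diversity_fraction(comp, threshold = 0.05)
  # 0.05 is not > 0.05: one contributor in ct1
  expect_equal(unname(div$percent_contributors["ct1"]), 100 * 1 / 3)
  expect_equal(unname(div$percent_contributors["ct2"]), 100)
  # 0.52/0.48 both contribute; NA ignored in the denominator
  expect_equal(unname(div$percent_contributors["ct3"]), 100)
  cnt <- div$per_family
  expect_equal(cnt$n_contributors[cnt$cell_type == "ct1"], 1L)
})

test_that("collapsing identical sequences sums counts and preserves totals", {
  toy <- toy_counts()
  coll <- collapse_identical(toy$counts, toy_annotation())
  expect_equal(nrow(coll), 2)
  expect_equal(unname(coll["Ile-TAT-2", ]), unname(colSums(toy$counts[1:2, ])))
  expect_equal(colSums(coll), colSums(toy$counts))
  # collapse-then-aggregate == aggregate directly at isoacceptor level
  expr <- relative_expression(toy$counts, toy$sheet, toy_annotation())
  iso_direct <- aggregate_expression(expr, toy_annotation(), "isoacceptor")
  sheet <- toy$sheet
  expr_coll <- relative_expression(coll, sheet, annotation = NULL,
                                   exclude_trx = FALSE)
  ann_groups <- data.frame(
    gene_name = rownames(coll),
    isotype = c("Arg", "Ile"), anticodon = c("TCT", "TAT"),
    transcript_group = c(4L, 2L), copy = 1L,
    identical_group_id = rownames(coll), is_trx = FALSE,
    is_high_confidence = TRUE, chrom = "chr1",
    start = c(1L, 2L), end = c(73L, 74L), strand = "+")
  class(ann_groups) <- c("trna_annotation", "data.frame")
  iso_via_coll <- aggregate_expression(expr_coll, ann_groups, "isoacceptor")
  expect_equal(iso_via_coll$values, iso_direct$values)
})

test_that("gene-resolution fractions sum to 1 on simulated data", {
  cfg <- sim_config(seed = 13, n_families = 15)
  ann <- generate_trna_annotation(cfg)
  chip <- simulate_chip_counts(ann, cfg)
  expr <- relative_expression(chip$counts, chip$sample_sheet, ann)
  expect_true(all(abs(colSums(expr$values) - 1) < 1e-9))
  expect_true(all(abs(colSums(expr$by_cell_type) - 1) < 1e-9))
})
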