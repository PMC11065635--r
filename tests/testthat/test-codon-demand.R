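# Codon demand: codon counting, expression-weighted usage, specific gene
# sets, cognate mapping, wobble-excluded correlation, matched/mismatched
# comparison, and the supply/demand ratio.

test_that("codon counting excludes stops and rejects malformed CDS", {
  cc <- codon_counts("ATGAAATAA")
  expect_equal(unname(cc[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(sum(cc), 2L)             # terminal TAA excluded
  expect_length(cc, 61)
  expect_false(any(names(cc) %in% stop_codons()))

  r1 <- codon_counts("ATGAA")
  expect_s3_class(r1, "codon_rejection")
  expect_match(r1$reason, "length not multiple of 3")

  r2 <- codon_counts("ATGTAAAAA")
  expect_s3_class(r2, "codon_rejection")
  expect_match(r2$reason, "internal stop")

  # permissive policy counts valid triplets and skips stops
  cc2 <- codon_counts("ATGTAAAAA", policy = "count")
  expect_equal(sum(cc2), 2L)
})

test_that("the codon count matrix logs rejected transcripts", {
  cds <- c(ok = "ATGAAATAA", short = "ATGAA", good = "ATGCCCGGG")
  M <- codon_count_matrix(cds)
  expect_equal(rownames(M), c("ok", "good"))
  rej <- attr(M, "rejected")
  expect_equal(rej$transcript, "short")
  # total sense codons = cds_length/3 minus the terminal stop if present
  expect_equal(sum(M["ok", ]), 2L)
  expect_equal(sum(M["good", ]), 3L)
})

test_that("weighted usage matches hand computation and the brute-force oracle", {
  # T1 {AAA:2} tpm 10, T2 {GGG:2} tpm 30 -> AAA 25%, GGG 75%
  M <- codon_count_matrix(c(T1 = "AAAAAA", T2 = "GGGGGG"))
  u <- weighted_codon_usage(M, c(T1 = 10, T2 = 30))
  expect_equal(unname(u["AAA"]), 25)
  expect_equal(unname(u["GGG"]), 75)
  expect_equal(sum(u), 100, tolerance = 1e-9)

  # equal tpm equals unweighted pooled frequency
  M2 <- codon_count_matrix(c(a = "ATGAAA", b = "ATGCCC"))
  u2 <- weighted_codon_usage(M2, c(a = 7, b = 7))
  pooled <- colSums(M2) / sum(M2)
  expect_equal(unname(u2), unname(100 * pooled), tolerance = 1e-12,
               ignore_attr = TRUE)

  # random fixtures against the transcript-by-transcript accumulator
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    Mr <- matrix(rpois(n * 61, 3), n, 61,
                 dimnames = list(paste0("t", 1:n), sense_codons()))
    tpm <- runif(n, 0, 50)
    expect_equal(unname(weighted_codon_usage(Mr, tpm)),
                 unname(weighted_usage_bruteforce(Mr, tpm)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(weighted_codon_usage(M, c(T1 = 0, T2 = 0)), "zero")
})

test_that("usage is invariant to tpm rescaling and tpm-zero transcripts", {
  set.seed(41)
  M <- matrix(rpois(10 * 61, 2), 10, 61,
              dimnames = list(paste0("t", 1:10), sense_codons()))
  tpm <- runif(10, 1, 100)
  u <- weighted_codon_usage(M, tpm)
  expect_equal(weighted_codon_usage(M, tpm * 1000), u, ignore_attr = TRUE)
  # adding a transcript with tpm = 0 changes nothing
  M0 <- rbind(M, t0 = rpois(61, 5))
  expect_equal(unname(weighted_codon_usage(M0, c(tpm, 0))), unname(u))
})

test_that("50-fold specific sets use the pseudocount and are disjoint", {
  tpm <- matrix(c(100, 40, 1, 0.5,
                  1, 1, 80, 0.5),
                ncol = 2,
                dimnames = list(c("hiA", "midA", "hiB", "lowBoth"),
                                c("A_r1", "B_r1")))
  sheet <- data.frame(sample = colnames(tpm), cell_type = c("A", "B"),
                      replicate = 1)
  suppressWarnings(
    sets <- specific_gene_sets(tpm, sheet, "A", "B", fold = 50, pseudo = 0.01))
  expect_true("hiA" %in% sets$set_a)      # (100.01)/(1.01) ~ 99 >= 50
  expect_false("midA" %in% sets$set_a)    # ~40-fold only
  expect_equal(sets$set_b, "hiB")
  expect_length(intersect(sets$set_a, sets$set_b), 0)
})

test_that("planted specific transcripts are recovered from the simulation", {
  cfg <- sim_config(seed = 59, n_transcripts = 400, n_specific = 15)
  tr <- simulate_translatome(cfg)
  sets <- specific_gene_sets(tr$tpm, tr$sample_sheet, "CT01", "CT02",
                             fold = 50, pseudo = 0.01)
  truth <- tr$truth$specific_transcripts
  realized <- tr$truth$realized_fold
  # transcripts whose realized post-normalization ratio clears the fold are in
  expected_a <- names(realized[["CT01"]])[realized[["CT01"]] >= 50]
  expect_true(all(expected_a %in% sets$set_a))
  # nothing outside the planted sets sneaks in
  expect_true(all(sets$set_a %in% truth[["CT01"]]))
  expect_true(all(sets$set_b %in% truth[["CT02"]]))
})

test_that("anticodons map to cognate codons by reverse complement", {
  expect_equal(anticodon_to_codon("TAT"), "ATA")
  expect_equal(anticodon_to_codon("TCT"), "AGA")
  expect_equal(anticodon_to_codon("AGC"), "GCT")
  expect_equal(anticodon_to_codon(c("TAT", "TCT")), c("ATA", "AGA"))
  expect_error(anticodon_to_codon("NNN"), "invalid")
})

test_that("codon-anticodon correlation excludes wobble-only codons", {
  usage <- setNames(seq(0.5, 3.5, length.out = 61), sense_codons())
  # families whose cognates are GCT (Ser-AGC? no: revcomp(AGC)=GCT), etc.
  fams <- c("Ala-AGC" = 5, "Gly-GCC" = 3, "Lys-TTT" = 2, "Ile-TAT" = 1)
  res <- codon_anticodon_correlation(fams, usage)
  inc <- res$pairs[res$pairs$included, ]
  expect_setequal(inc$codon, c("GCT", "GGC", "AAA", "ATA"))
  # every codon with no exact-cognate family is recorded as wobble-only
  wob <- res$pairs[!res$pairs$included, ]
  expect_true(all(wob$exclusion_reason == "wobble-only decoding"))
  expect_equal(nrow(res$pairs), 61)

  # an unexpressed family is excluded with its own reason
  fams0 <- c(fams, "Val-AAC" = 0)
  res0 <- codon_anticodon_correlation(fams0, usage)
  gtt <- res0$pairs[res0$pairs$codon == "GTT", ]
  expect_false(gtt$included)
  expect_equal(gtt$exclusion_reason, "family not expressed")

  expect_error(codon_anticodon_correlation(fams[1:2], usage), "fewer than 3")
})

test_that("correlation equals the rank oracle and hits 1 on monotone data", {
  usage <- setNames(rep(0.1, 61), sense_codons())
  fams <- c("Ala-AGC" = 1, "Gly-GCC" = 2, "Lys-TTT" = 3, "Ile-TAT" = 4)
  usage[c("GCT", "GGC", "AAA", "ATA")] <- c(1, 2, 3, 4)  # monotone
  expect_equal(codon_anticodon_correlation(fams, usage)$rho, 1)

  set.seed(71)
  for (i in 1:20) {
    x <- runif(8); y <- runif(8)
    expect_equal(cor(x, y, method = "spearman"),
                 spearman_bruteforce(x, y), tolerance = 1e-12)
    # with ties, average ranks
    xt <- sample(1:4, 8, replace = TRUE)
    expect_equal(cor(xt, y, method = "spearman"),
                 spearman_bruteforce(xt, y), tolerance = 1e-12)
  }
})

test_that("matched vs mismatched correlations compare by Mann-Whitney", {
  # identical matched and mismatched values -> p = 1
  rho <- matrix(0.5, 3, 3, dimnames = list(paste0("c", 1:3), paste0("c", 1:3)))
  expect_equal(matched_mismatched_test(rho)$p, 1)

  # matched far above mismatched -> smallest exact two-sided p, U extreme
  rho2 <- matrix(seq(0.01, 0.16, by = 0.01), 4, 4,
                 dimnames = list(paste0("c", 1:4), paste0("c", 1:4)))
  diag(rho2) <- c(0.9, 0.91, 0.92, 0.93)
  res <- matched_mismatched_test(rho2)
  # exact enumeration: all 4 matched above all 12 mismatched
  # two-sided p = 2 / choose(16, 4)
  expect_equal(res$p, 2 / choose(16, 4), tolerance = 1e-10)
  expect_equal(unname(res$U), 48)  # 4 * 12, maximal

  # pooled multiset is invariant under cell-type permutation
  perm <- c(3, 1, 4, 2)
  rho_p <- rho2[perm, perm]
  res_p <- matched_mismatched_test(rho_p)
  expect_equal(sort(unname(c(res_p$matched, res_p$mismatched))),
               sort(unname(c(res$matched, res$mismatched))))
})

test_that("supply/demand ratio divides pool percent by usage percent", {
  usage <- setNames(rep(1, 61), sense_codons())
  usage["ATA"] <- 1; usage["AGA"] <- 2
  lv <- c("Ile-TAT" = 2, "Arg-TCT" = 1)
  sd <- supply_demand_ratio(lv, usage)
  expect_equal(sd$ratio[sd$isoacceptor == "Ile-TAT"], 2.0)
  expect_equal(sd$ratio[sd$isoacceptor == "Arg-TCT"], 0.5)
  expect_equal(sd$cognate_codon, c("ATA", "AGA"))
  usage0 <- usage; usage0["ATA"] <- 0
  expect_error(supply_demand_ratio(lv, usage0), "zero codon usage")
})

test_that("usage vectors of two synthetic cell types are highly correlated", {
  # shared base codon frequencies -> near-identical global usage
  cfg <- sim_config(seed = 83, n_transcripts = 500, n_specific = 10)
  tr <- simulate_translatome(cfg)
  M <- codon_count_matrix(tr$cds)
  sheet <- tr$sample_sheet
  u <- lapply(c("CT01", "CT02"), function(ctn) {
    tpm <- rowMeans(tr$tpm[, sheet$sample[sheet$cell_type == ctn]])
    weighted_codon_usage(M, tpm)
  })
  expect_gt(cor(u[[1]], u[[2]]), 0.99)
  expect_equal(pearson_bruteforce(u[[1]], u[[2]]), cor(u[[1]], u[[2]]),
               tolerance = 1e-12)
})
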