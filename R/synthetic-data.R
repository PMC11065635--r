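# Synthetic-study generator: a gtRNAdb-style tRNA gene catalogue, Pol III
# ChIP-seq count matrices with negative-binomial noise and planted group
# differences, and translatomes (CDS + TPM) with planted cell-type-specific
# transcripts and planted codon-usage shifts. Every planted effect is recorded
# in a ground-truth object so downstream recovery can be scored exactly.

#' Configuration for the synthetic study
#'
#' Bundles and validates every knob of the generator. The defaults describe
#' the emulated study design: two ChIP biological replicates per cell type,
#' three translatome replicates, four cell types split into a neuronal and a
#' non-neuronal class, read depth and dispersion typical of tRNA-locus ChIP
#' counts, and mouse-scale CDS lengths.
#'
#' @param seed integer root seed. Per-component streams are derived from it so
#'   adding one generator never perturbs another.
#' @param n_families number of isoacceptor families to draw (<= 61).
#' @param genes_per_family integer range (length 2), genes per family.
#' @param n_identical_groups number of transcript groups that must contain
#'   >= 2 genes with identical mature sequence.
#' @param n_cell_types number of cell types.
#' @param n_replicates ChIP biological replicates per cell type.
#' @param library_depth expected tRNA-mapped reads per ChIP sample.
#' @param nb_dispersion negative-binomial dispersion phi in
#'   \eqn{Var = \mu + \phi \mu^2}; 0 degenerates to Poisson.
#' @param planted_trna_log2fc planted |log2 fold change| between the two
#'   sample groups for differential tRNA genes.
#' @param n_planted_trna number of planted differential tRNA genes.
#' @param trx_fraction fraction of extra catalogue entries named with the tRX
#'   prefix (ambiguous isotype/anticodon).
#' @param low_confidence_fraction fraction of genes flagged low-confidence.
#' @param n_transcripts number of protein-coding transcripts in the
#'   translatome.
#' @param cds_length_codons integer range of CDS lengths in codons
#'   (including start and stop).
#' @param tpm_logsd log-scale standard deviation of transcript expression.
#' @param n_translatome_replicates translatome replicates per cell type.
#' @param planted_codon sense codon whose relative frequency is shifted in the
#'   planted gene set, or NULL for none.
#' @param planted_codon_shift additive shift in relative codon frequency
#'   within the planted set (0 < shift < 1 when a codon is planted).
#' @param planted_set_size size of the planted (codon-shifted) gene set.
#' @param n_specific cell-type-specific transcripts planted per cell type for
#'   the first two cell types.
#' @param specific_fold TPM fold difference imposed on specific transcripts
#'   before per-sample renormalization.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 30L,
                       genes_per_family = c(1L, 6L),
                       n_identical_groups = 5L,
                       n_cell_types = 4L,
                       n_replicates = 2L,
                       library_depth = 5e5,
                       nb_dispersion = 0.05,
                       planted_trna_log2fc = 1,
                       n_planted_trna = 10L,
                       trx_fraction = 0.05,
                       low_confidence_fraction = 0.15,
                       n_transcripts = 2000L,
                       cds_length_codons = c(100L, 500L),
                       tpm_logsd = 1.5,
                       n_translatome_replicates = 3L,
                       planted_codon = NULL,
                       planted_codon_shift = 0,
                       planted_set_size = 100L,
                       n_specific = 20L,
                       specific_fold = 50) {
  fail_if(!is_count(seed, min = 0L), "seed must be a non-negative integer")
  fail_if(!is_count(n_families), "n_families must be a positive integer")
  fail_if(n_families > 61L, "n_families cannot exceed the 61 sense codons")
  fail_if(!is_range(genes_per_family), "genes_per_family must be an increasing integer range >= 1")
  fail_if(!is_count(n_identical_groups, min = 0L), "n_identical_groups must be >= 0")
  fail_if(n_identical_groups > n_families,
          "n_identical_groups cannot exceed n_families")
  fail_if(!is_count(n_cell_types, min = 2L), "n_cell_types must be >= 2")
  fail_if(!is_count(n_replicates), "n_replicates must be >= 1")
  fail_if(!is.numeric(library_depth) || library_depth < 1,
          "library_depth must be >= 1")
  fail_if(!is.numeric(nb_dispersion) || nb_dispersion < 0,
          "nb_dispersion must be >= 0")
  fail_if(!is.numeric(planted_trna_log2fc) || length(planted_trna_log2fc) != 1L,
          "planted_trna_log2fc must be a single number")
  fail_if(!is_count(n_planted_trna, min = 0L), "n_planted_trna must be >= 0")
  fail_if(trx_fraction < 0 || trx_fraction >= 1, "trx_fraction must be in [0, 1)")
  fail_if(low_confidence_fraction < 0 || low_confidence_fraction >= 1,
          "low_confidence_fraction must be in [0, 1)")
  fail_if(!is_count(n_transcripts), "n_transcripts must be a positive integer")
  fail_if(!is_range(cds_length_codons, min = 3L),
          "cds_length_codons must be an integer range with minimum >= 3")
  fail_if(tpm_logsd < 0, "tpm_logsd must be >= 0")
  fail_if(!is_count(n_translatome_replicates), "n_translatome_replicates must be >= 1")
  if (!is.null(planted_codon)) {
    fail_if(!planted_codon %in% sense_codons(),
            "planted_codon must be one of the 61 sense codons, got '%s'",
            as.character(planted_codon))
    fail_if(planted_codon_shift <= 0 || planted_codon_shift >= 1,
            "planted_codon_shift must be in (0, 1) when a codon is planted")
  }
  fail_if(!is_count(planted_set_size, min = 0L), "planted_set_size must be >= 0")
  fail_if(!is.null(planted_codon) && planted_set_size > n_transcripts,
          "planted_set_size cannot exceed n_transcripts")
  fail_if(!is_count(n_specific, min = 0L), "n_specific must be >= 0")
  fail_if(specific_fold < 1, "specific_fold must be >= 1")

  structure(list(
    seed = as.integer(seed), n_families = as.integer(n_families),
    genes_per_family = as.integer(genes_per_family),
    n_identical_groups = as.integer(n_identical_groups),
    n_cell_types = as.integer(n_cell_types),
    n_replicates = as.integer(n_replicates),
    library_depth = library_depth, nb_dispersion = nb_dispersion,
    planted_trna_log2fc = planted_trna_log2fc,
    n_planted_trna = as.integer(n_planted_trna),
    trx_fraction = trx_fraction,
    low_confidence_fraction = low_confidence_fraction,
    n_transcripts = as.integer(n_transcripts),
    cds_length_codons = as.integer(cds_length_codons),
    tpm_logsd = tpm_logsd,
    n_translatome_replicates = as.integer(n_translatome_replicates),
    planted_codon = planted_codon,
    planted_codon_shift = planted_codon_shift,
    planted_set_size = as.integer(planted_set_size),
    n_specific = as.integer(n_specific), specific_fold = specific_fold
  ), class = "sim_config")
}

#' Generate a gtRNAdb-style tRNA gene catalogue
#'
#' Draws isoacceptor families (isotype + anticodon), assigns each family a
#' number of gene copies, groups a configurable number of them into
#' identical-mature-sequence transcript groups (shared group number, copies
#' -1, -2, ...), and appends tRX (ambiguous) entries. Gene names follow the
#' gtRNAdb dialect \code{tRNA-<Iso>-<Anticodon>-<group>-<copy>}.
#'
#' @param config a \code{sim_config}.
#' @return data.frame of class \code{trna_annotation} with columns
#'   \code{gene_name}, \code{isotype}, \code{anticodon},
#'   \code{transcript_group}, \code{copy}, \code{identical_group_id},
#'   \code{is_trx}, \code{is_high_confidence}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}.
#' @export
generate_trna_annotation <- function(config) {
  fail_if(!inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(stream_seed(config$seed, "annotation"), {
    tab <- codon_table()
    fam_codons <- sample(tab$codon, config$n_families)
    fam_iso <- tab$amino_acid3[match(fam_codons, tab$codon)]
    fam_anti <- anticodon_to_codon(fam_codons)  # revcomp is its own inverse

    rows <- vector("list", config$n_families)
    for (i in seq_len(config$n_families)) {
      k <- sample(seq(config$genes_per_family[1], config$genes_per_family[2]), 1L)
      if (i <= config$n_identical_groups) k <- max(k, 2L)
      if (i <= config$n_identical_groups) {
        # first transcript group of this family holds two identical genes
        grp  <- c(1L, 1L, seq_len(max(k - 2L, 0L)) + 1L)
        copy <- c(1L, 2L, rep(1L, max(k - 2L, 0L)))
      } else {
        grp  <- seq_len(k)
        copy <- rep(1L, k)
      }
      rows[[i]] <- data.frame(
        isotype = fam_iso[i], anticodon = fam_anti[i],
        transcript_group = grp, copy = copy, is_trx = FALSE,
        stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)

    n_trx <- round(config$trx_fraction * nrow(ann))
    if (n_trx > 0) {
      ann <- rbind(ann, data.frame(
        isotype = NA_character_, anticodon = "NNN",
        transcript_group = seq_len(n_trx), copy = 1L, is_trx = TRUE,
        stringsAsFactors = FALSE))
    }

    ann$gene_name <- ifelse(
      ann$is_trx,
      sprintf("tRX-NNN-%d-%d", ann$transcript_group, ann$copy),
      sprintf("tRNA-%s-%s-%d-%d", ann$isotype, ann$anticodon,
              ann$transcript_group, ann$copy))
    ann$identical_group_id <- ifelse(
      ann$is_trx, ann$gene_name,
      sprintf("%s-%s-%d", ann$isotype, ann$anticodon, ann$transcript_group))

    ann$is_high_confidence <-
      !ann$is_trx & (runif(nrow(ann)) >= config$low_confidence_fraction)

    n <- nrow(ann)
    ann$chrom <- sample(paste0("chr", c(1:19, "X")), n, replace = TRUE)
    ann$start <- sort(sample.int(2e6, n)) * 50L
    ann$end <- ann$start + 72L
    ann$strand <- sample(c("+", "-"), n, replace = TRUE)

    ann <- ann[, c("gene_name", "isotype", "anticodon", "transcript_group",
                   "copy", "identical_group_id", "is_trx",
                   "is_high_confidence", "chrom", "start", "end", "strand")]
    rownames(ann) <- ann$gene_name
    class(ann) <- c("trna_annotation", "data.frame")
    ann
  })
}

#' Sample sheet of the synthetic ChIP study
#'
#' Cell types CT01..CTk; the first half is classed neuronal (differential
#' group "A"), the second half non-neuronal (group "B").
#' @keywords internal
chip_sample_sheet <- function(config) {
  ct <- sprintf("CT%02d", seq_len(config$n_cell_types))
  cls <- ifelse(seq_along(ct) <= ceiling(length(ct) / 2),
                "neuronal", "non_neuronal")
  grp <- ifelse(cls == "neuronal", "A", "B")
  data.frame(
    sample = paste0(rep(ct, each = config$n_replicates), "_rep",
                    rep(seq_len(config$n_replicates), length(ct))),
    cell_type = rep(ct, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(ct)),
    group = rep(grp, each = config$n_replicates),
    class = rep(cls, each = config$n_replicates),
    stringsAsFactors = FALSE)
}

# Planted differential tRNA genes: derived deterministically from the root
# seed so the ground truth can be regenerated and cross-checked exactly.
derive_chip_truth <- function(annotation, config) {
  with_seed(stream_seed(config$seed, "chip_truth"), {
    eligible <- annotation$gene_name[!annotation$is_trx]
    n <- min(config$n_planted_trna, length(eligible))
    genes <- sort(sample(eligible, n))
    sign <- sample(c(1, -1), n, replace = TRUE)
    data.frame(gene = genes,
               log2fc = sign * config$planted_trna_log2fc,
               stringsAsFactors = FALSE)
  })
}

#' Simulate Pol III ChIP-seq read counts over tRNA gene loci
#'
#' Each gene receives a log-normal baseline weight shared across cell types;
#' planted genes differ by \code{planted_trna_log2fc} between group "A" and
#' group "B" cell types. Per-sample expected counts are the weights scaled to
#' \code{library_depth}, and replicate counts are drawn negative-binomially
#' with dispersion \code{nb_dispersion} (Poisson when 0).
#'
#' @param annotation a \code{trna_annotation}.
#' @param config a \code{sim_config}.
#' @param truth optional planted-gene table (as returned in
#'   \code{$truth$differential_trna_genes}); derived from the seed when NULL.
#' @return list of class \code{chip_sim} with elements \code{counts}
#'   (genes x samples integer matrix), \code{sample_sheet}, \code{truth}
#'   (list with \code{differential_trna_genes} and \code{underpowered}), and
#'   \code{config}.
#' @export
simulate_chip_counts <- function(annotation, config, truth = NULL) {
  fail_if(!inherits(config, "sim_config"), "config must be a sim_config")
  fail_if(nrow(annotation) == 0L, "annotation is empty")
  if (is.null(truth)) truth <- derive_chip_truth(annotation, config)

  sheet <- chip_sample_sheet(config)
  with_seed(stream_seed(config$seed, "chip_counts"), {
    n_genes <- nrow(annotation)
    base <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
    names(base) <- annotation$gene_name

    # per-cell-type weights; planted genes split the fold change
    # symmetrically so neither group is systematically deeper
    ct <- unique(sheet$cell_type)
    grp_of_ct <- sheet$group[match(ct, sheet$cell_type)]
    w <- matrix(base, nrow = n_genes, ncol = length(ct),
                dimnames = list(annotation$gene_name, ct))
    if (nrow(truth) > 0) {
      idx <- match(truth$gene, annotation$gene_name)
      fail_if(anyNA(idx), "truth names genes absent from the annotation")
      for (j in seq_along(ct)) {
        half <- if (grp_of_ct[j] == "A") truth$log2fc / 2 else -truth$log2fc / 2
        w[idx, j] <- w[idx, j] * 2^half
      }
    }

    mu <- sweep(w, 2L, colSums(w), "/") * config$library_depth
    counts <- matrix(0L, n_genes, nrow(sheet),
                     dimnames = list(annotation$gene_name, sheet$sample))
    for (s in seq_len(nrow(sheet))) {
      m <- mu[, sheet$cell_type[s]]
      counts[, s] <- if (config$nb_dispersion == 0) {
        rpois(n_genes, m)
      } else {
        rnbinom(n_genes, mu = m, size = 1 / config$nb_dispersion)
      }
    }

    underpowered <- character(0)
    if (nrow(truth) > 0) {
      planted_mu <- mu[match(truth$gene, rownames(mu)), , drop = FALSE]
      weak <- apply(planted_mu, 1L, min) < 1
      if (any(weak)) {
        underpowered <- truth$gene[weak]
        warning(sprintf(
          "library_depth too small to realize planted effects for %d gene(s)",
          sum(weak)), call. = FALSE)
      }
    }

    structure(list(counts = counts, sample_sheet = sheet,
                   truth = list(differential_trna_genes = truth,
                                underpowered = underpowered),
                   config = config),
              class = "chip_sim")
  })
}

#' Simulate a translatome: CDS sequences and TPM tables
#'
#' Every CDS is a start codon, a body drawn from a shared base codon
#' frequency over the 61 sense codons (hence no internal stop), and one
#' terminal stop. Transcripts in the planted set have the planted codon's
#' relative frequency raised additively by \code{planted_codon_shift}
#' (remaining codons renormalized). TPMs are log-normal per cell type with
#' replicate noise and sum to 1e6 per sample; cell-type-specific transcripts
#' get a \code{specific_fold} expression ratio imposed before per-sample
#' renormalization (ground truth stores realized post-normalization ratios).
#'
#' @param config a \code{sim_config}.
#' @param truth ignored; present for symmetry (ground truth is derived from
#'   the seed).
#' @return list of class \code{translatome_sim} with elements \code{cds}
#'   (named character), \code{tpm} (transcripts x samples), \code{sample_sheet},
#'   \code{base_codon_freq}, \code{truth} (list: \code{specific_transcripts}
#'   per cell type, \code{realized_fold}, \code{planted_set},
#'   \code{biased_codons}), and \code{config}.
#' @export
simulate_translatome <- function(config, truth = NULL) {
  fail_if(!inherits(config, "sim_config"), "config must be a sim_config")
  fail_if(config$cds_length_codons[1] < 3L,
          "cds_length_codons must allow at least start + one codon + stop")

  with_seed(stream_seed(config$seed, "translatome"), {
    codons <- sense_codons()
    n <- config$n_transcripts
    ids <- sprintf("T%05d", seq_len(n))

    base_freq <- rgamma(61, shape = 5)
    base_freq <- base_freq / sum(base_freq)
    names(base_freq) <- codons

    planted_set <- character(0)
    biased <- list()
    if (!is.null(config$planted_codon) && config$planted_set_size > 0) {
      planted_set <- sort(sample(ids, config$planted_set_size))
      biased[[config$planted_codon]] <- config$planted_codon_shift
    }

    shifted_freq <- base_freq
    if (length(planted_set) > 0) {
      pc <- config$planted_codon
      target <- base_freq[pc] + config$planted_codon_shift
      fail_if(target >= 1, "planted_codon_shift pushes frequency above 1")
      shifted_freq[-match(pc, codons)] <-
        base_freq[-match(pc, codons)] * (1 - target) / (1 - base_freq[pc])
      shifted_freq[pc] <- target
    }

    lens <- sample(seq(config$cds_length_codons[1], config$cds_length_codons[2]),
                   n, replace = TRUE)
    stops <- sample(stop_codons(), n, replace = TRUE)
    is_planted <- ids %in% planted_set
    cds <- character(n)
    for (i in seq_len(n)) {
      p <- if (is_planted[i]) shifted_freq else base_freq
      body <- sample(codons, lens[i] - 2L, replace = TRUE, prob = p)
      cds[i] <- paste0("ATG", paste(body, collapse = ""), stops[i])
    }
    names(cds) <- ids

    # TPM: transcript baseline (log-normal) x mild cell-type tilt x replicate noise
    ct <- sprintf("CT%02d", seq_len(config$n_cell_types))
    sheet <- data.frame(
      sample = paste0(rep(ct, each = config$n_translatome_replicates), "_rep",
                      rep(seq_len(config$n_translatome_replicates), length(ct))),
      cell_type = rep(ct, each = config$n_translatome_replicates),
      replicate = rep(seq_len(config$n_translatome_replicates), length(ct)),
      stringsAsFactors = FALSE)

    baseline <- rlnorm(n, meanlog = 3, sdlog = config$tpm_logsd)
    tilt <- matrix(rlnorm(n * length(ct), 0, 0.1), n, length(ct),
                   dimnames = list(ids, ct))
    expr_ct <- baseline * tilt

    specific <- list()
    if (config$n_specific > 0 && length(ct) >= 2) {
      pool <- sample(ids, 2L * config$n_specific)
      specific[[ct[1]]] <- sort(pool[seq_len(config$n_specific)])
      specific[[ct[2]]] <- sort(pool[config$n_specific + seq_len(config$n_specific)])
      # imposed on expression before per-sample renormalization
      expr_ct[specific[[ct[1]]], ct[2]] <-
        expr_ct[specific[[ct[1]]], ct[1]] / config$specific_fold
      expr_ct[specific[[ct[2]]], ct[1]] <-
        expr_ct[specific[[ct[2]]], ct[2]] / config$specific_fold
    }

    raw <- matrix(0, n, nrow(sheet), dimnames = list(ids, sheet$sample))
    for (s in seq_len(nrow(sheet))) {
      noise <- rlnorm(n, 0, 0.2)
      raw[, s] <- expr_ct[, sheet$cell_type[s]] * noise
    }
    tpm <- sweep(raw, 2L, colSums(raw), "/") * 1e6

    realized_fold <- list()
    if (length(specific) == 2L) {
      m1 <- rowMeans(tpm[, sheet$sample[sheet$cell_type == ct[1]], drop = FALSE])
      m2 <- rowMeans(tpm[, sheet$sample[sheet$cell_type == ct[2]], drop = FALSE])
      realized_fold[[ct[1]]] <- m1[specific[[ct[1]]]] / m2[specific[[ct[1]]]]
      realized_fold[[ct[2]]] <- m2[specific[[ct[2]]]] / m1[specific[[ct[2]]]]
    }

    structure(list(cds = cds, tpm = tpm, sample_sheet = sheet,
                   base_codon_freq = base_freq,
                   truth = list(specific_transcripts = specific,
                                realized_fold = realized_fold,
                                planted_set = planted_set,
                                biased_codons = biased),
                   config = config),
              class = "translatome_sim")
  })
}
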