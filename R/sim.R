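#' Configuration for the synthetic multi-omic cohort generator
#'
#' Returns the generator settings as a validated list. Defaults emulate a
#' modest antidepressant-response cohort: 111 subjects, 10 latent topics, and
#' feature panels scaled to desk size (the statistical structure, not the
#' feature count, is what downstream stages assume).
#'
#' @param n_subjects number of subjects (default 111).
#' @param n_topics number of planted latent topics K (default 10).
#' @param n_genes,n_cpgs,n_snps,n_genesets panel sizes.
#' @param n_redundant_sets near-duplicate genesets appended to exercise the
#'   merge rule (default 2).
#' @param noise_sd Gaussian noise SD on the log-expression scale.
#' @param methyl_noise_sd Gaussian noise SD on the logit (methylation) scale.
#' @param methyl_scale scale applied to the topic signal on the logit scale.
#' @param expr_effect planted differential-expression shift, log units.
#' @param beta_effect target planted group difference in beta-value units.
#' @param diff_frac fraction of genes and of CpGs planted as differential.
#' @param n_qtl number of planted cis-QTL effects.
#' @param qtl_beta planted QTL effect size (signal units per allele).
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param missing_rate genotype missingness rate per call.
#' @param n_hwe_violations SNPs generated off Hardy-Weinberg equilibrium.
#' @param hwe_inbreeding inbreeding coefficient F used for violating SNPs
#'   (excess homozygosity).
#' @param response_topic index of the topic the response label loads on.
#' @param response_slope,response_intercept logistic link from the
#'   standardized response-topic score to the responder probability.
#' @param age_effect,sex_effect SDs of per-feature covariate coefficients on
#'   the log / logit scale (0 disables covariate effects).
#' @param madrs_slope strength of the link between the response-topic score
#'   and the MADRS improvement ratio within each label group.
#' @param n_chromosomes,chrom_length genome layout dimensions (bp).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 111L, n_topics = 10L, n_genes = 150L,
                       n_cpgs = 200L, n_snps = 500L, n_genesets = 20L,
                       n_redundant_sets = 2L,
                       noise_sd = 0.3, methyl_noise_sd = 0.3,
                       methyl_scale = 0.5,
                       expr_effect = 1.0, beta_effect = 0.05,
                       diff_frac = 0.1,
                       n_qtl = 5L, qtl_beta = 0.8,
                       maf_range = c(0.1, 0.5), missing_rate = 0.005,
                       n_hwe_violations = 0L, hwe_inbreeding = 0.5,
                       response_topic = 1L, response_slope = 2,
                       response_intercept = 0,
                       age_effect = 0.02, sex_effect = 0.1,
                       madrs_slope = 0.8,
                       n_chromosomes = 4L, chrom_length = 2e7) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  dims <- c("n_subjects", "n_topics", "n_genes", "n_cpgs", "n_snps",
            "n_genesets", "n_chromosomes")
  for (d in dims) {
    if (length(cfg[[d]]) != 1L || cfg[[d]] < 1) {
      stop(sprintf("sim config: '%s' must be a positive integer", d))
    }
  }
  if (cfg$n_topics > min(cfg$n_subjects, cfg$n_genes, cfg$n_cpgs)) {
    stop("sim config: n_topics must not exceed min(n_subjects, n_genes, n_cpgs)")
  }
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("sim config: maf_range must lie within (0, 0.5]")
  }
  if (cfg$noise_sd < 0 || cfg$methyl_noise_sd < 0) {
    stop("sim config: noise SDs must be non-negative")
  }
  if (cfg$diff_frac < 0 || cfg$diff_frac > 1) {
    stop("sim config: diff_frac must lie in [0, 1]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("sim config: missing_rate must lie in [0, 1)")
  }
  if (cfg$response_topic < 1 || cfg$response_topic > cfg$n_topics) {
    stop("sim config: response_topic out of range")
  }
  invisible(cfg)
}

#' Generate a synthetic multi-omic cohort with planted ground truth
#'
#' Draws a complete cohort with the statistical structure every downstream
#' stage assumes: strictly positive expression (log-normal around the planted
#' topic signal `W alpha rho`), methylation beta values in (0,1) (logistic
#' squash of the planted signal), genotype dosages under Hardy-Weinberg
#' equilibrium (except a configurable set of violating SNPs), a responder
#' label drawn from a logistic link on one topic's subject scores, and
#' 10-item MADRS questionnaires at week 0 and week 8 consistent with the
#' >= 50 percent total-score-reduction responder rule.
#'
#' Each data modality draws from its own RNG stream derived from the master
#' seed, so e.g. enlarging the SNP panel does not perturb the expression
#' draws. The same `config` and `seed` reproduce the cohort exactly.
#'
#' @param config a [sim_config()] list.
#' @param seed master integer seed.
#' @return list of class `"igem_cohort"` with elements `expression`
#'   (genes x subjects, positive), `methylation` (CpGs x subjects, in (0,1)),
#'   `genotypes` (a `"genotype_table"`), `phenotypes` (data.frame with
#'   response, age, sex and per-item MADRS at weeks 0 and 8), `layout`
#'   (chromosomes, genes, cpgs, snps), `genesets` (named list), and `truth`
#'   (planted `W`, `alpha`, `H2`, `rho`, differential feature ids, QTL
#'   effects, labels; see [planted_truth_report()]).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(as.integer(seed))
  streams <- sample.int(.Machine$integer.max - 1L, 8L)

  N <- config$n_subjects; K <- config$n_topics
  G <- config$n_genes; C <- config$n_cpgs; M <- config$n_snps
  S <- config$n_genesets

  gene_ids <- sprintf("gene%04d", seq_len(G))
  cpg_ids <- sprintf("cg%05d", seq_len(C))
  snp_ids <- sprintf("rs%06d", seq_len(M))
  subj_ids <- sprintf("subj%03d", seq_len(N))

  ## stream 1: genome layout --------------------------------------------------
  set.seed(streams[1L])
  layout <- sim_layout(config, gene_ids, cpg_ids, snp_ids)

  ## stream 2: genesets -------------------------------------------------------
  set.seed(streams[2L])
  gs <- sim_genesets(config, gene_ids)
  genesets <- gs$genesets
  rho_true <- gs$rho  # S x G membership normalized over genes

  ## stream 3: planted factors and per-feature covariate coefficients --------
  set.seed(streams[3L])
  W <- matrix(stats::rgamma(N * K, 2, 2), N, K,
              dimnames = list(subj_ids, paste0("topic", seq_len(K))))
  alpha <- matrix(stats::rgamma(K * S, 2, 2), K, S,
                  dimnames = list(paste0("topic", seq_len(K)), rownames(rho_true)))
  H2 <- matrix(stats::rgamma(K * C, 2, 2), K, C,
               dimnames = list(paste0("topic", seq_len(K)), cpg_ids))
  gene_age <- rnorm(G, 0, config$age_effect)
  gene_sex <- rnorm(G, 0, config$sex_effect)
  cpg_age <- rnorm(C, 0, config$age_effect)
  cpg_sex <- rnorm(C, 0, config$sex_effect)
  cpg_baseline <- runif(C, -1.5, 1.5)

  ## stream 4: genotypes ------------------------------------------------------
  set.seed(streams[4L])
  geno <- sim_genotypes(config, snp_ids, subj_ids)

  ## stream 5: labels and covariates ------------------------------------------
  set.seed(streams[5L])
  age <- round(runif(N, 20, 64))
  sex <- rbinom(N, 1L, 0.5)
  k0 <- config$response_topic
  z <- as.vector(scale(W[, k0]))
  p_res <- plogis(config$response_intercept + config$response_slope * z)
  labels <- rbinom(N, 1L, p_res)

  ## stream 6: planted effects (which features / which QTL pairs) -------------
  set.seed(streams[6L])
  n_dg <- floor(config$diff_frac * G)
  n_dc <- floor(config$diff_frac * C)
  diff_genes <- if (n_dg > 0) sort(sample(gene_ids, n_dg)) else character(0)
  # planted differential CpGs are drawn from gene-proximal sites: the
  # methylation differences the pipeline models are cis to selected genes
  diff_cpgs <- character(0)
  if (n_dc > 0) {
    prox <- vapply(seq_len(C), function(i) {
      any(feature_distance(layout$cpgs$chrom[i], layout$cpgs$start[i],
                           layout$genes) <= 500000)
    }, logical(1))
    pool <- cpg_ids[prox]
    diff_cpgs <- sort(sample(pool, min(n_dc, length(pool))))
  }
  qtl <- sim_qtl_effects(config, layout, gene_ids, cpg_ids)

  ## stream 7: expression -----------------------------------------------------
  set.seed(streams[7L])
  log_signal <- W %*% alpha %*% rho_true            # N x G, planted topic part
  if (n_dg > 0) {
    sgn <- rep(c(1, -1), length.out = n_dg)
    idx <- match(diff_genes, gene_ids)
    log_signal[, idx] <- log_signal[, idx] +
      outer(labels, sgn * config$expr_effect)
  }
  gq <- qtl[qtl$feature_type == "gene", , drop = FALSE]
  for (i in seq_len(nrow(gq))) {
    dos <- geno$dosage_complete[, gq$snp_id[i]]
    g <- match(gq$feature_id[i], gene_ids)
    log_signal[, g] <- log_signal[, g] + gq$beta[i] * dos
  }
  if (config$age_effect > 0 || config$sex_effect > 0) {
    log_signal <- log_signal + outer(age - mean(age), gene_age) +
      outer(sex, gene_sex)
  }
  if (config$noise_sd > 0) {
    log_signal <- log_signal + matrix(rnorm(N * G, 0, config$noise_sd), N, G)
  }
  expression <- t(exp(log_signal))                  # genes x subjects
  dimnames(expression) <- list(gene_ids, subj_ids)

  ## stream 8: methylation ----------------------------------------------------
  set.seed(streams[8L])
  topic_part <- W %*% H2
  logit_signal <- config$methyl_scale * (topic_part - mean(topic_part))
  logit_signal <- sweep(logit_signal, 2L, cpg_baseline, "+")
  if (length(diff_cpgs) > 0) {
    # planted CpGs are response-driven sites: anchored at beta ~= 0.5 (where
    # the logistic slope is known), with the topic load damped so the group
    # difference dominates, and an offset sized so the realized mean
    # difference clears beta_effect
    idx <- match(diff_cpgs, cpg_ids)
    damp <- 0.3
    logit_signal[, idx] <- damp * config$methyl_scale *
      (topic_part[, idx, drop = FALSE] - mean(topic_part))
    sgn <- rep(c(1, -1), length.out = length(diff_cpgs))
    off <- qlogis(pmin(0.5 + 1.6 * config$beta_effect, 0.99))
    logit_signal[, idx] <- logit_signal[, idx] + outer(labels, sgn * off)
  }
  cq <- qtl[qtl$feature_type == "cpg", , drop = FALSE]
  for (i in seq_len(nrow(cq))) {
    dos <- geno$dosage_complete[, cq$snp_id[i]]
    cc <- match(cq$feature_id[i], cpg_ids)
    logit_signal[, cc] <- logit_signal[, cc] + cq$beta[i] * dos
  }
  if (config$age_effect > 0 || config$sex_effect > 0) {
    logit_signal <- logit_signal + outer(age - mean(age), cpg_age) +
      outer(sex, cpg_sex)
  }
  if (config$methyl_noise_sd > 0) {
    logit_signal <- logit_signal +
      matrix(rnorm(N * C, 0, config$methyl_noise_sd), N, C)
  }
  methylation <- t(plogis(logit_signal))            # CpGs x subjects
  dimnames(methylation) <- list(cpg_ids, subj_ids)

  ## MADRS questionnaires (same stream as labels' covariates would be
  ## confusing; they are phenotype data, drawn after everything else on
  ## stream 5's successor state is avoided by reseeding from stream 5 + 1)
  set.seed(streams[5L] + 1L)
  madrs <- sim_madrs(labels, z, config$madrs_slope)

  phenotypes <- data.frame(subject_id = subj_ids, response = labels,
                           age = age, sex = sex,
                           madrs_total_w0 = madrs$total_w0,
                           madrs_total_w8 = madrs$total_w8,
                           stringsAsFactors = FALSE)
  phenotypes <- cbind(phenotypes, madrs$items_w0, madrs$items_w8)

  truth <- list(W = W, alpha = alpha, H2 = H2, rho = rho_true,
                genesets = genesets,
                response_topic_index = k0,
                differential_gene_ids = diff_genes,
                differential_cpg_ids = diff_cpgs,
                qtl_effects = qtl[, c("snp_id", "feature_id", "beta")],
                labels = labels,
                covariates = data.frame(age = age, sex = sex),
                maf = geno$maf_config,
                hwe_violating_snps = geno$violating)

  structure(list(expression = expression, methylation = methylation,
                 genotypes = geno$table, phenotypes = phenotypes,
                 layout = layout, genesets = genesets, truth = truth,
                 config = config, seed = as.integer(seed)),
            class = "igem_cohort")
}

sim_layout <- function(config, gene_ids, cpg_ids, snp_ids) {
  G <- length(gene_ids); C <- length(cpg_ids); M <- length(snp_ids)
  nchr <- config$n_chromosomes; L <- config$chrom_length
  chroms <- data.frame(name = paste0("chr", seq_len(nchr)),
                       length = rep(as.integer(L), nchr),
                       stringsAsFactors = FALSE)
  gene_chr <- sample(chroms$name, G, replace = TRUE)
  gene_len <- sample(5000:80000, G, replace = TRUE)
  gene_start <- vapply(gene_len, function(l) {
    sample.int(L - l - 2000L, 1L) + 1000L
  }, integer(1))
  genes <- data.frame(chrom = gene_chr, start = gene_start,
                      end = gene_start + gene_len, id = gene_ids,
                      strand = sample(c("+", "-"), G, replace = TRUE),
                      stringsAsFactors = FALSE)
  anchor_point <- function(n, frac_anchored = 0.8, spread = 3e5) {
    anchored <- runif(n) < frac_anchored
    ag <- sample.int(G, n, replace = TRUE)
    pos <- ifelse(anchored,
                  pmin(pmax(genes$start[ag] +
                              round(runif(n, -spread, spread)), 1), L - 2),
                  sample.int(L - 2L, n, replace = TRUE))
    list(pos = as.integer(pos),
         chrom = ifelse(anchored, genes$chrom[ag],
                        sample(chroms$name, n, replace = TRUE)))
  }
  cp <- anchor_point(C)
  cpgs <- data.frame(chrom = cp$chrom, start = cp$pos, end = cp$pos + 1L,
                     id = cpg_ids, stringsAsFactors = FALSE)
  sp <- anchor_point(M, frac_anchored = 0.7)
  alleles <- matrix(replicate(M, sample(c("A", "C", "G", "T"), 2L)), nrow = 2L)
  snps <- data.frame(chrom = sp$chrom, start = sp$pos, end = sp$pos + 1L,
                     id = snp_ids, ref = alleles[1L, ], alt = alleles[2L, ],
                     stringsAsFactors = FALSE)
  list(chromosomes = chroms, genes = genes, cpgs = cpgs, snps = snps)
}

sim_genesets <- function(config, gene_ids) {
  G <- length(gene_ids); S <- config$n_genesets
  set_ids <- sprintf("GS%03d", seq_len(S))
  # each gene joins one primary set plus occasional extras
  memb <- matrix(FALSE, S, G, dimnames = list(set_ids, gene_ids))
  primary <- sample.int(S, G, replace = TRUE)
  memb[cbind(primary, seq_len(G))] <- TRUE
  extra <- which(runif(G) < 0.3)
  if (length(extra)) {
    memb[cbind(sample.int(S, length(extra), replace = TRUE), extra)] <- TRUE
  }
  # any empty set picks up a random handful of genes
  for (s in which(rowSums(memb) == 0)) {
    memb[s, sample.int(G, max(3L, G %/% S))] <- TRUE
  }
  genesets <- apply(memb, 1L, function(r) gene_ids[r], simplify = FALSE)
  # near-duplicate sets exercise the recursive merge rule downstream
  nr <- config$n_redundant_sets
  if (nr > 0) {
    base <- sample.int(S, nr, replace = TRUE)
    for (j in seq_len(nr)) {
      src <- genesets[[base[j]]]
      keep <- src[runif(length(src)) < 0.9]
      if (length(keep) < 2L) keep <- src
      genesets[[sprintf("GS%03d", S + j)]] <- keep
    }
  }
  rho <- memb / rowSums(memb)
  list(genesets = genesets, rho = rho)
}

sim_genotypes <- function(config, snp_ids, subj_ids) {
  M <- length(snp_ids); N <- length(subj_ids)
  maf <- runif(M, config$maf_range[1], config$maf_range[2])
  violating <- character(0)
  dos <- matrix(0L, N, M, dimnames = list(subj_ids, snp_ids))
  nv <- min(config$n_hwe_violations, M)
  if (nv > 0) violating <- snp_ids[sample.int(M, nv)]
  f <- config$hwe_inbreeding
  for (j in seq_len(M)) {
    p <- maf[j]
    if (snp_ids[j] %in% violating) {
      # excess homozygosity via inbreeding coefficient F
      probs <- c((1 - p)^2 + f * p * (1 - p),
                 2 * p * (1 - p) * (1 - f),
                 p^2 + f * p * (1 - p))
      dos[, j] <- sample(0:2, N, replace = TRUE, prob = probs)
    } else {
      dos[, j] <- rbinom(N, 2L, p)
    }
  }
  dosage_complete <- dos
  if (config$missing_rate > 0) {
    miss <- matrix(runif(N * M) < config$missing_rate, N, M)
    dos[miss] <- NA
  }
  storage.mode(dos) <- "double"
  tab <- structure(list(dosage = dos, snp_ids = snp_ids,
                        subject_ids = subj_ids,
                        counted_allele = rep(NA_character_, M)),
                   class = "genotype_table")
  list(table = tab, dosage_complete = dosage_complete,
       maf_config = setNames(maf, snp_ids), violating = violating)
}

sim_qtl_effects <- function(config, layout, gene_ids, cpg_ids) {
  n <- config$n_qtl
  empty <- data.frame(snp_id = character(0), feature_id = character(0),
                      feature_type = character(0), beta = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  snps <- layout$snps
  # strictly cis: targets with no SNP inside the window are skipped
  pick_cis_snp <- function(chrom, center) {
    cand <- which(snps$chrom == chrom &
                    abs(snps$start - center) <= 500000L)
    if (!length(cand)) return(NA_integer_)
    cand[which.min(abs(snps$start[cand] - center))]
  }
  n_gene <- ceiling(n / 2); n_cpg <- n - n_gene
  tg <- sample(gene_ids, min(n_gene, length(gene_ids)))
  tc <- sample(cpg_ids, min(n_cpg, length(cpg_ids)))
  rows <- list()
  used <- integer(0)
  for (g in tg) {
    gi <- match(g, layout$genes$id)
    si <- pick_cis_snp(layout$genes$chrom[gi], layout$genes$start[gi])
    if (is.na(si) || si %in% used) next
    used <- c(used, si)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = snps$id[si], feature_id = g, feature_type = "gene",
      beta = config$qtl_beta * sample(c(-1, 1), 1L), stringsAsFactors = FALSE)
  }
  for (cpg in tc) {
    ci <- match(cpg, layout$cpgs$id)
    si <- pick_cis_snp(layout$cpgs$chrom[ci], layout$cpgs$start[ci])
    if (is.na(si) || si %in% used) next
    used <- c(used, si)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = snps$id[si], feature_id = cpg, feature_type = "cpg",
      beta = config$qtl_beta * sample(c(-1, 1), 1L), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# distribute a total score over n items, each capped at max_item, by a
# multinomial draw followed by deterministic overflow reallocation
distribute_items <- function(total, n_items = 10L, max_item = 6L) {
  total <- min(total, n_items * max_item)
  if (total == 0) return(integer(n_items))
  x <- as.vector(rmultinom(1L, total, rep(1 / n_items, n_items)))
  over <- sum(pmax(x - max_item, 0L))
  x <- pmin(x, max_item)
  while (over > 0L) {
    room <- which(x < max_item)
    take <- room[seq_len(min(over, length(room)))]
    x[take] <- x[take] + 1L
    over <- over - length(take)
  }
  x
}

sim_madrs <- function(labels, z, slope) {
  N <- length(labels)
  total_w0 <- sample(22:40, N, replace = TRUE)
  # improvement ratio correlated with the response topic within each group
  u <- plogis(slope * z + rnorm(N))
  ratio <- ifelse(labels == 1, 0.5 + 0.45 * u, -0.2 + 0.65 * u)
  total_w8 <- ifelse(labels == 1,
                     floor(total_w0 * (1 - ratio)),
                     pmin(ceiling(total_w0 * (1 - ratio)), 60L))
  total_w8 <- pmax(total_w8, 0L)
  items_w0 <- t(vapply(total_w0, distribute_items, integer(10L)))
  items_w8 <- t(vapply(total_w8, distribute_items, integer(10L)))
  colnames(items_w0) <- paste0("madrs_w0_item", 1:10)
  colnames(items_w8) <- paste0("madrs_w8_item", 1:10)
  list(total_w0 = total_w0, total_w8 = as.integer(total_w8),
       items_w0 = as.data.frame(items_w0), items_w8 = as.data.frame(items_w8))
}

#' Flat table of the planted effects in a synthetic cohort
#'
#' One row per planted effect: QTL rows carry `(snp_id, feature_id, beta)`,
#' differential rows carry the feature id. Recovery tests join against this
#' table.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @return data.frame with columns `kind`, `id`, `feature_id`, `beta`.
#' @export
planted_truth_report <- function(truth) {
  qtl <- truth$qtl_effects
  rows <- list()
  if (nrow(qtl)) {
    rows$qtl <- data.frame(kind = "qtl", id = qtl$snp_id,
                           feature_id = qtl$feature_id, beta = qtl$beta,
                           stringsAsFactors = FALSE)
  }
  if (length(truth$differential_gene_ids)) {
    rows$dg <- data.frame(kind = "differential_gene",
                          id = truth$differential_gene_ids,
                          feature_id = NA_character_, beta = NA_real_,
                          stringsAsFactors = FALSE)
  }
  if (length(truth$differential_cpg_ids)) {
    rows$dc <- data.frame(kind = "differential_cpg",
                          id = truth$differential_cpg_ids,
                          feature_id = NA_character_, beta = NA_real_,
                          stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(kind = character(0), id = character(0),
                      feature_id = character(0), beta = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits the on-disk forms every pipeline stage reads: `expression.tsv` and
#' `methylation.tsv` (features x subjects), `genotypes.raw` (PLINK .raw
#' dialect), `genes.bed` / `cpgs.bed` / `snps.bed` (BED-like TSV, 0-based
#' half-open), `genesets.gmt`, `phenotypes.tsv` and `truth.json`.
#'
#' @param cohort an `"igem_cohort"`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_matrix(cohort$expression, fp("expression.tsv"), "gene_id")
  write_matrix(cohort$methylation, fp("methylation.tsv"), "cpg_id")
  write_genotypes(cohort$genotypes, fp("genotypes.raw"),
                  sex = cohort$phenotypes$sex + 1L)
  write_layout(cohort$layout$genes, fp("genes.bed"))
  write_layout(cohort$layout$cpgs, fp("cpgs.bed"))
  write_layout(cohort$layout$snps, fp("snps.bed"))
  write_gmt(cohort$genesets, fp("genesets.gmt"))
  write.table(cohort$phenotypes, fp("phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth_json <- list(
    W = unname(truth$W), alpha = unname(truth$alpha), H2 = unname(truth$H2),
    rho = unname(truth$rho),
    response_topic_index = truth$response_topic_index,
    differential_gene_ids = truth$differential_gene_ids,
    differential_cpg_ids = truth$differential_cpg_ids,
    qtl_effects = truth$qtl_effects,
    labels = truth$labels,
    covariates = truth$covariates,
    hwe_violating_snps = truth$hwe_violating_snps)
  jsonlite::write_json(truth_json, fp("truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
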