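#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Probabilities are
#' computed by the standard recurrence over heterozygote counts (numerically
#' stable for large samples); the test is symmetric in the two homozygote
#' classes, and a monomorphic SNP returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts.
#' @return exact p-value in \[0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) ||
      any(c(n_AA, n_Aa, n_aa) != round(c(n_AA, n_Aa, n_aa)))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype observation required")
  rare <- 2L * min(n_AA, n_aa) + n_Aa     # rare-allele copies
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # start at the mode-ish midpoint and fill both directions by recurrence:
  # P(h+2)/P(h) = (rare-h)(2n-rare-h) / ((h+2)(h+1))
  mid <- hets[which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))]
  im <- match(mid, hets)
  probs[im] <- 1
  if (im < length(hets)) {
    for (i in seq.int(im, length(hets) - 1L)) {
      h <- hets[i]
      probs[i + 1L] <- probs[i] * (rare - h) * (2 * n - rare - h) /
        ((h + 2) * (h + 1))
    }
  }
  if (im > 1L) {
    for (i in seq.int(im, 2L)) {
      h <- hets[i]
      probs[i - 1L] <- probs[i] * h * (h - 1) /
        ((rare - h + 2) * (2 * n - rare - h + 2))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# orient dosages to count the minor allele; returns flipped matrix + freq
orient_minor <- function(dosage) {
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    dosage[, flip] <- 2 - dosage[, flip]
    freq[flip] <- 1 - freq[flip]
  }
  list(dosage = dosage, maf = freq, flipped = flip)
}

#' Per-SNP quality control
#'
#' Orients every SNP to count the minor allele, then removes SNPs failing
#' any of: missing call rate above `missing_rate`, minor allele frequency
#' below `maf`, or exact Hardy-Weinberg p-value below `hwe_p`. Removal is
#' attributed to the first failing criterion in that order.
#'
#' @param geno a `"genotype_table"` (see [read_genotypes()]) or a subjects x
#'   SNPs dosage matrix.
#' @param hwe_p retain SNPs with HWE exact p >= this (default 0.001).
#' @param missing_rate retain SNPs with missingness <= this (default 0.01).
#' @param maf retain SNPs with MAF >= this (default 0.05).
#' @return list with `dosage` (filtered, minor-allele oriented), `maf`
#'   (retained SNPs), `report` (per-criterion removal counts), `removed`
#'   (data.frame `snp_id`, `reason`).
#' @export
snp_qc <- function(geno, hwe_p = 0.001, missing_rate = 0.01, maf = 0.05) {
  dos <- if (inherits(geno, "genotype_table")) geno$dosage else as.matrix(geno)
  ori <- orient_minor(dos)
  dos <- ori$dosage
  miss <- colMeans(is.na(dos))
  hwe <- vapply(seq_len(ncol(dos)), function(j) {
    x <- dos[, j]
    hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  reason <- rep(NA_character_, ncol(dos))
  reason[is.na(reason) & miss > missing_rate] <- "missing_rate"
  reason[is.na(reason) & ori$maf < maf] <- "maf"
  reason[is.na(reason) & hwe < hwe_p] <- "hwe"
  keep <- is.na(reason)
  report <- c(input = ncol(dos),
              removed_missing = sum(reason == "missing_rate", na.rm = TRUE),
              removed_maf = sum(reason == "maf", na.rm = TRUE),
              removed_hwe = sum(reason == "hwe", na.rm = TRUE),
              retained = sum(keep))
  list(dosage = dos[, keep, drop = FALSE], maf = ori$maf[keep],
       hwe_p = hwe[keep], report = report,
       removed = data.frame(snp_id = colnames(dos)[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

# OLS of y on x plus covariates (complete cases); Wald stats for x
ols_assoc <- function(y, x, covariates = NULL) {
  X <- cbind(intercept = 1, x = x)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  ok <- complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p || sd(X[, "x"]) == 0) {
    return(c(beta = NA_real_, t = NA_real_, p_value = NA_real_, n = n))
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    return(c(beta = NA_real_, t = NA_real_, p_value = NA_real_, n = n))
  }
  bhat <- qr.coef(qrx, y)
  res <- y - X %*% bhat
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tval <- bhat[["x"]] / se
  c(beta = bhat[["x"]], t = tval, p_value = 2 * pt(-abs(tval), n - p), n = n)
}

#' Genome-wide scan of SNP association with responder status
#'
#' Per QC-passed SNP, ordinary least squares of the response label on the
#' minor-allele dosage with age and sex as covariates; the Wald p-value on
#' the dosage coefficient is reported. Missingness is handled per SNP by
#' complete cases. No global multiple-testing correction is applied; the
#' "top set" is selected at a fixed nominal threshold.
#'
#' @param dosage subjects x SNPs matrix (QC-passed, minor-allele oriented).
#' @param labels binary response vector.
#' @param covariates data.frame with `age` and `sex`.
#' @param top_p nominal threshold defining the top set (default 1e-4).
#' @return data.frame: `snp_id`, `beta`, `t`, `p_value`, `n`, `top` flag.
#' @export
response_snp_scan <- function(dosage, labels, covariates, top_p = 1e-4) {
  stopifnot(nrow(dosage) == length(labels))
  covs <- as.matrix(covariates[, c("age", "sex")])
  rows <- t(vapply(seq_len(ncol(dosage)), function(j) {
    ols_assoc(as.numeric(labels), dosage[, j], covs)
  }, numeric(4)))
  out <- data.frame(snp_id = colnames(dosage) %||%
                      as.character(seq_len(ncol(dosage))),
                    beta = rows[, "beta"], t = rows[, "t"],
                    p_value = rows[, "p_value"], n = as.integer(rows[, "n"]),
                    stringsAsFactors = FALSE)
  out$top <- !is.na(out$p_value) & out$p_value < top_p
  out
}

#' Regression of topic scores on top SNPs under two genotype codings
#'
#' For every (SNP, topic) pair, OLS of the topic score on the coded genotype
#' with age and sex as covariates. `"additive"` uses the minor-allele dosage
#' 0/1/2; `"major_presence"` groups heterozygotes with major-allele
#' homozygotes (coded 0) against minor-allele homozygotes (coded 1), probing
#' recessive-like effects of the minor allele.
#'
#' @param dosage subjects x SNPs matrix (minor-allele oriented), typically
#'   restricted to the top response SNPs.
#' @param W subjects x topics score matrix.
#' @param covariates data.frame with `age` and `sex`.
#' @param coding `"additive"` or `"major_presence"`.
#' @return data.frame: `snp_id`, `topic`, `coding`, `beta`, `t`, `p_value`,
#'   `n`.
#' @export
snp_topic_regression <- function(dosage, W, covariates,
                                 coding = c("additive", "major_presence")) {
  coding <- match.arg(coding)
  stopifnot(nrow(dosage) == nrow(W))
  covs <- as.matrix(covariates[, c("age", "sex")])
  snps <- colnames(dosage) %||% as.character(seq_len(ncol(dosage)))
  topics <- colnames(W) %||% paste0("topic", seq_len(ncol(W)))
  rows <- list()
  for (j in seq_len(ncol(dosage))) {
    x <- dosage[, j]
    if (coding == "major_presence") x <- as.numeric(x == 2)
    for (k in seq_len(ncol(W))) {
      a <- ols_assoc(W[, k], x, covs)
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snps[j], topic = topics[k], coding = coding,
        beta = a[["beta"]], t = a[["t"]], p_value = a[["p_value"]],
        n = as.integer(a[["n"]]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(is.na(out$beta))) {
    ig_log("snp_topic_regression: %d pair(s) with constant regressor -> NA",
           sum(is.na(out$beta)))
  }
  out
}

#' cis-QTL scan
#'
#' For every feature, OLS of the feature values on each SNP's minor-allele
#' dosage (age and sex as covariates) over the SNPs within `window` bp of
#' the feature; BH adjustment is applied within each feature's cis set and
#' significant pairs are reported at `fdr`. Passing `window = NULL` tests
#' every SNP against every feature (used for topic scores and MADRS
#' responses, which have no genomic position).
#'
#' @param features subjects x features matrix (expression for eQTL,
#'   methylation for mQTL, topic scores, MADRS change ratios).
#' @param dosage subjects x SNPs matrix (QC-passed, oriented).
#' @param layout list with a `snps` data.frame; plus `genes`/`cpgs` holding
#'   the feature coordinates (matched by feature id) when `window` is set.
#' @param window cis window in bp (default 500000), or `NULL` for
#'   genome-wide.
#' @param fdr within-feature BH level (default 0.1).
#' @param covariates data.frame with `age` and `sex`.
#' @return data.frame: `feature_id`, `snp_id`, `distance`, `beta`, `t`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
cis_qtl <- function(features, dosage, layout, covariates,
                    window = 500000L, fdr = 0.1) {
  stopifnot(nrow(features) == nrow(dosage))
  covs <- as.matrix(covariates[, c("age", "sex")])
  snps <- layout$snps[match(colnames(dosage), layout$snps$id), , drop = FALSE]
  feat_ids <- colnames(features) %||% as.character(seq_len(ncol(features)))
  coords <- rbind(
    if (!is.null(layout$genes)) layout$genes[c("chrom", "start", "end", "id")],
    if (!is.null(layout$cpgs)) layout$cpgs[c("chrom", "start", "end", "id")])
  rows <- list()
  for (f in seq_along(feat_ids)) {
    if (is.null(window)) {
      cand <- seq_len(ncol(dosage))
      dists <- rep(NA_real_, length(cand))
    } else {
      fi <- match(feat_ids[f], coords$id)
      if (is.na(fi)) stop("no coordinates for feature ", feat_ids[f])
      iv <- coords[fi, ]
      d <- ifelse(snps$chrom != iv$chrom, Inf,
                  ifelse(snps$start < iv$start, iv$start - snps$start,
                         ifelse(snps$start >= iv$end,
                                snps$start - (iv$end - 1L), 0)))
      cand <- which(d <= window)
      dists <- as.numeric(d[cand])
      if (!length(cand)) {
        ig_log("cis_qtl: feature %s has no cis SNP", feat_ids[f])
        next
      }
    }
    st <- t(vapply(cand, function(j) {
      ols_assoc(features[, f], dosage[, j], covs)
    }, numeric(4)))
    df <- data.frame(feature_id = feat_ids[f],
                     snp_id = colnames(dosage)[cand],
                     distance = dists,
                     beta = st[, "beta"], t = st[, "t"],
                     p_value = st[, "p_value"],
                     stringsAsFactors = FALSE)
    df$p_adjusted <- bh_adjust(df$p_value)
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(0), snp_id = character(0),
                      distance = numeric(0), beta = numeric(0), t = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < fdr
  rownames(out) <- NULL
  out
}
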