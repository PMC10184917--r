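#' MADRS change ratios and responder classification
#'
#' Computes, per subject, the per-item and total change ratio
#' `(week0 - week8) / week0` (positive = improvement) and classifies
#' responders by total ratio >= 0.5. Items with a week-0 score of 0 have an
#' undefined ratio and are returned as `NA`; subjects with a week-0 total of
#' 0 are flagged and get an `NA` responder status.
#'
#' @param week0,week8 integer matrices, subjects x 10 items (scores 0--6).
#' @return list with `item_ratio` (subjects x items), `total_ratio`,
#'   `responder` (logical), `undefined` (subjects with zero baseline total).
#' @export
madrs_change <- function(week0, week8) {
  week0 <- as.matrix(week0); week8 <- as.matrix(week8)
  stopifnot(all(dim(week0) == dim(week8)))
  if (any(week0 < 0 | week0 > 6, na.rm = TRUE) ||
      any(week8 < 0 | week8 > 6, na.rm = TRUE)) {
    stop("MADRS items must be integers between 0 and 6")
  }
  item_ratio <- (week0 - week8) / week0
  item_ratio[week0 == 0] <- NA_real_
  colnames(item_ratio) <- paste0("item", seq_len(ncol(item_ratio)))
  t0 <- rowSums(week0); t8 <- rowSums(week8)
  total_ratio <- ifelse(t0 == 0, NA_real_, (t0 - t8) / t0)
  undefined <- which(t0 == 0)
  if (length(undefined)) {
    ig_log("madrs_change: %d subject(s) with zero baseline total flagged",
           length(undefined))
  }
  list(item_ratio = item_ratio, total_ratio = total_ratio,
       responder = total_ratio >= 0.5, undefined = undefined)
}

#' Benjamini-Hochberg adjustment with NaN handling
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1. `NA`/`NaN`
#' entries are excluded from the family and restored in place.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA/NaN allowed).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Topic--response association (Spearman)
#'
#' Spearman correlation between each topic's subject scores and the binary
#' responder label, with BH adjustment across the K topics. Constant topic
#' columns yield `NA` statistics.
#'
#' @param W subjects x topics score matrix.
#' @param labels binary responder vector.
#' @param fdr significance level on the adjusted p (default 0.05).
#' @return data.frame: `topic`, `rho`, `p_value`, `p_adjusted`, `direction`
#'   (+1 higher in responders), `significant`.
#' @export
topic_response_association <- function(W, labels, fdr = 0.05) {
  stopifnot(nrow(W) == length(labels))
  labels <- as.numeric(labels)
  if (length(unique(labels[!is.na(labels)])) != 2L) {
    stop("labels must be binary")
  }
  res <- lapply(seq_len(ncol(W)), function(k) {
    w <- W[, k]
    if (sd(w, na.rm = TRUE) == 0 || all(is.na(w))) {
      return(data.frame(topic = k, rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(w, labels, method = "spearman",
                                    exact = FALSE))
    data.frame(topic = k, rho = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$topic <- colnames(W) %||% as.character(out$topic)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$direction <- sign(out$rho)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < fdr
  out
}

# Pearson association of each column of A with each column of Y,
# pairwise-complete; returns long data.frame.
pairwise_pearson <- function(A, Y, a_name = "a", y_name = "y") {
  an <- colnames(A) %||% paste0(a_name, seq_len(ncol(A)))
  yn <- colnames(Y) %||% paste0(y_name, seq_len(ncol(Y)))
  rows <- list()
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(Y))) {
      x <- A[, i]; y <- Y[, j]
      ok <- complete.cases(x, y)
      n <- sum(ok)
      if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          a = an[i], y = yn[j], r = NA_real_, p_value = NA_real_, n = n,
          stringsAsFactors = FALSE)
        next
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        a = an[i], y = yn[j], r = unname(ct$estimate), p_value = ct$p.value,
        n = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c(a_name, y_name)
  out
}

#' Topic--MADRS association (Pearson)
#'
#' Pearson correlation between each topic's subject scores and each MADRS
#' item change ratio (plus the total), pairwise-complete over subjects, with
#' BH adjustment over all tested (topic, item) pairs.
#'
#' @param W subjects x topics score matrix.
#' @param madrs result of [madrs_change()] (or a subjects x items matrix of
#'   change ratios).
#' @param fdr significance level on the adjusted p (default 0.05).
#' @return data.frame: `topic`, `item`, `r`, `p_value`, `n`, `p_adjusted`,
#'   `significant`.
#' @export
topic_madrs_association <- function(W, madrs, fdr = 0.05) {
  Y <- if (is.list(madrs) && !is.null(madrs$item_ratio)) {
    cbind(madrs$item_ratio, total = madrs$total_ratio)
  } else {
    as.matrix(madrs)
  }
  stopifnot(nrow(W) == nrow(Y))
  out <- pairwise_pearson(W, Y, a_name = "topic", y_name = "item")
  out$p_adjusted <- bh_adjust(out$p_value)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < fdr
  out
}

#' Top features per topic with relative scores
#'
#' Ranks features within each topic by factor score and reports the top `n`
#' with scores relative to the topic's maximum (the top feature scores 1).
#' Ties are broken by feature id.
#'
#' @param H topics x features basis matrix (`H1` for genes, `H2` for CpGs).
#' @param n features per topic (default 10; capped at the feature count).
#' @return data.frame: `topic`, `rank`, `feature_id`, `score`,
#'   `relative_score`.
#' @export
top_features <- function(H, n = 10L) {
  feats <- colnames(H) %||% as.character(seq_len(ncol(H)))
  topics <- rownames(H) %||% paste0("topic", seq_len(nrow(H)))
  n <- min(n, ncol(H))
  rows <- lapply(seq_len(nrow(H)), function(k) {
    sc <- H[k, ]
    ord <- order(-sc, feats)
    idx <- ord[seq_len(n)]
    mx <- sc[idx[1L]]
    data.frame(topic = topics[k], rank = seq_len(n), feature_id = feats[idx],
               score = unname(sc[idx]),
               relative_score = if (mx > 0) unname(sc[idx]) / mx else
                 rep(NA_real_, n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Most correlated proximal gene for a CpG
#'
#' Among genes within `window` bp of the CpG, returns the one whose
#' log-expression has the largest absolute Pearson correlation with the
#' CpG's beta values (used to substitute gene names for top methylation
#' sites in reports).
#'
#' @param cpg_id CpG identifier.
#' @param beta CpGs x subjects matrix.
#' @param log_expr genes x subjects matrix.
#' @param layout list with `genes` and `cpgs`.
#' @param window proximity window in bp (default 500000).
#' @return list with `gene_id` (NA if no proximal gene), `r`, and
#'   `candidates` (proximal gene ids).
#' @export
map_cpg_to_correlated_gene <- function(cpg_id, beta, log_expr, layout,
                                       window = 500000L) {
  ci <- match(cpg_id, layout$cpgs$id)
  if (is.na(ci)) stop("unknown CpG id: ", cpg_id)
  genes <- layout$genes[layout$genes$id %in% rownames(log_expr), ,
                        drop = FALSE]
  d <- feature_distance(layout$cpgs$chrom[ci], layout$cpgs$start[ci], genes)
  cand <- genes$id[d <= window]
  if (!length(cand)) {
    ig_log("map_cpg_to_correlated_gene: no proximal gene for %s", cpg_id)
    return(list(gene_id = NA_character_, r = NA_real_,
                candidates = character(0)))
  }
  y <- beta[cpg_id, ]
  r <- vapply(cand, function(g) {
    x <- log_expr[g, ]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  if (all(is.na(r))) {
    return(list(gene_id = NA_character_, r = NA_real_, candidates = cand))
  }
  best <- which.max(abs(r))
  list(gene_id = cand[best], r = unname(r[best]), candidates = cand)
}

#' Association of top genes with MADRS item changes
#'
#' Pearson correlation between the expression of each topic's top genes and
#' each MADRS item change ratio, BH-adjusted over all tested pairs, with
#' significance reported at two tiers (FDR < 0.05 and < 0.1).
#'
#' @param top_genes data.frame from [top_features()] on `H1` (columns
#'   `topic`, `feature_id`), or a character vector of gene ids.
#' @param log_expr genes x subjects matrix.
#' @param madrs result of [madrs_change()].
#' @param fdr_tiers two significance levels (default 0.05 and 0.1).
#' @return data.frame: `topic`, `gene_id`, `item`, `r`, `p_value`, `n`,
#'   `p_adjusted`, `sig_strict`, `sig_lenient`.
#' @export
gene_madrs_association <- function(top_genes, log_expr, madrs,
                                   fdr_tiers = c(0.05, 0.1)) {
  if (is.character(top_genes)) {
    top_genes <- data.frame(topic = NA_character_, feature_id = top_genes,
                            stringsAsFactors = FALSE)
  }
  genes <- unique(top_genes$feature_id)
  genes <- genes[genes %in% rownames(log_expr)]
  if (!length(genes)) stop("none of the top genes are in log_expr")
  E <- t(log_expr[genes, , drop = FALSE])       # subjects x genes
  Y <- cbind(madrs$item_ratio, total = madrs$total_ratio)
  out <- pairwise_pearson(E, Y, a_name = "gene_id", y_name = "item")
  out$p_adjusted <- bh_adjust(out$p_value)
  out$sig_strict <- !is.na(out$p_adjusted) & out$p_adjusted < min(fdr_tiers)
  out$sig_lenient <- !is.na(out$p_adjusted) & out$p_adjusted < max(fdr_tiers)
  topic_of <- top_genes$topic[match(out$gene_id, top_genes$feature_id)]
  out <- cbind(topic = topic_of, out)
  out
}

#' Hierarchical clustering of subjects on topic scores
#'
#' Optionally min-max normalizes each column to \[0, 1\] (constant columns
#' map to 0), then performs agglomerative clustering (Euclidean distance,
#' average linkage by default) and returns the tree and leaf order.
#'
#' @param scores subjects x columns matrix (e.g. selected topics of `W`).
#' @param normalize min-max normalize columns first (default TRUE).
#' @param method linkage passed to [stats::hclust()] (default "average").
#' @return list with `tree` (hclust), `leaf_order` (row indices), `labels`,
#'   `scores` (the possibly normalized matrix).
#' @export
cluster_patients <- function(scores, normalize = TRUE, method = "average") {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) {
    rownames(scores) <- paste0("s", seq_len(nrow(scores)))
  }
  if (normalize) {
    scores <- apply(scores, 2L, function(x) {
      rng <- range(x)
      if (rng[1] == rng[2]) {
        ig_log("cluster_patients: constant column mapped to 0")
        return(rep(0, length(x)))
      }
      (x - rng[1]) / (rng[2] - rng[1])
    })
  }
  tree <- hclust(dist(scores), method = method)
  list(tree = tree, leaf_order = tree$order,
       labels = rownames(scores) %||% as.character(seq_len(nrow(scores))),
       scores = scores)
}

#' Export a patient clustering tree as newick
#'
#' @param clust result of [cluster_patients()].
#' @param path output file.
#' @export
write_patient_tree <- function(clust, path) {
  phy <- ape::as.phylo(clust$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
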