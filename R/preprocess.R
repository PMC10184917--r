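# Row-wise Welch two-sample t-tests. M is features x subjects.
# Degenerate rows (zero within-group variance in both groups) get p = 1.
welch_rows <- function(M, labels) {
  labels <- as.integer(labels)
  if (length(labels) != ncol(M)) stop("labels length must match subjects")
  if (length(unique(labels)) < 2L) {
    stop("both groups must be present in 'labels'")
  }
  g1 <- labels == 1L; g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 subjects per group")
  m1 <- rowMeans(M[, g1, drop = FALSE]); m2 <- rowMeans(M[, g2, drop = FALSE])
  v1 <- rowSums((M[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((M[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    warning(sprintf("%d feature(s) with zero within-group variance in both groups; p set to 1",
                    sum(degenerate)))
    p[degenerate] <- 1
    tt[degenerate] <- 0
  }
  data.frame(feature_id = rownames(M) %||% as.character(seq_len(nrow(M))),
             diff = m1 - m2, t = tt, df = df, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential expression filter
#'
#' Welch two-sample t-test per gene between responders and non-responders on
#' the log-expression matrix, as a documented stand-in for a count-model fit
#' (the pipeline ingests already-normalized matrices). A gene passes when its
#' p-value is at or below `p_threshold` *and* it appears in at least one
#' geneset, since genes outside the geneset universe cannot enter the
#' geneset-embedded factorization.
#'
#' @param log_expr genes x subjects matrix of log expression.
#' @param labels binary vector (1 = responder), one per subject.
#' @param genesets named list of gene-id vectors.
#' @param p_threshold nominal significance gate (default 0.05).
#' @param p_values optional precomputed per-gene p-values (e.g. from an
#'   external count-model fit), overriding the Welch test.
#' @return data.frame: `feature_id`, `diff` (group mean difference, log
#'   units), `t`, `df`, `p_value`, `in_geneset`, `pass`.
#' @export
differential_expression <- function(log_expr, labels, genesets,
                                    p_threshold = 0.05, p_values = NULL) {
  if (anyNA(log_expr)) stop("log_expr must not contain missing values")
  stats <- welch_rows(log_expr, labels)
  if (!is.null(p_values)) {
    if (length(p_values) != nrow(stats)) {
      stop("p_values must have one entry per gene")
    }
    stats$p_value <- as.numeric(p_values)
  }
  universe <- unique(unlist(genesets, use.names = FALSE))
  stats$in_geneset <- stats$feature_id %in% universe
  stats$pass <- stats$p_value <= p_threshold & stats$in_geneset
  stats
}

#' Differential methylation filter
#'
#' A CpG passes when the absolute responder/non-responder difference in mean
#' beta value is at least `delta_threshold` *and* the CpG lies within
#' `window` bp of at least one selected gene. A Welch p-value is reported for
#' downstream use; an optional gate on it (off by default) can be enabled.
#'
#' @param beta CpGs x subjects matrix of beta values in \[0, 1\].
#' @param labels binary responder vector.
#' @param selected_genes character vector of gene ids that passed
#'   [differential_expression()].
#' @param layout list with `genes` and `cpgs` data.frames (see
#'   [read_layout()]).
#' @param delta_threshold minimum absolute group beta difference
#'   (default 0.025; the comparison is `>=`).
#' @param window proximity window in bp (default 500000).
#' @param p_gate if `TRUE` additionally require `p_value <= p_threshold`.
#' @param p_threshold gate level used when `p_gate = TRUE`.
#' @return data.frame: `feature_id`, `diff` (beta units), `p_value`,
#'   `proximal`, `pass`.
#' @export
differential_methylation <- function(beta, labels, selected_genes, layout,
                                     delta_threshold = 0.025,
                                     window = 500000L, p_gate = FALSE,
                                     p_threshold = 0.05) {
  if (anyNA(beta)) stop("beta must not contain missing values")
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0, 1]")
  stats <- welch_rows(beta, labels)
  genes <- layout$genes[layout$genes$id %in% selected_genes, , drop = FALSE]
  cpgs <- layout$cpgs[match(stats$feature_id, layout$cpgs$id), , drop = FALSE]
  stats$proximal <- vapply(seq_len(nrow(stats)), function(i) {
    any(feature_distance(cpgs$chrom[i], cpgs$start[i], genes) <= window)
  }, logical(1))
  stats$pass <- abs(stats$diff) >= delta_threshold & stats$proximal
  if (p_gate) stats$pass <- stats$pass & stats$p_value <= p_threshold
  stats
}

# gap in bp between a point feature and each gene interval (0 if inside);
# Inf for genes on other chromosomes. Intervals are 0-based half-open.
feature_distance <- function(chrom, pos, genes) {
  if (nrow(genes) == 0L) return(numeric(0))
  d <- ifelse(genes$chrom != chrom, Inf,
              ifelse(pos < genes$start, genes$start - pos,
                     ifelse(pos >= genes$end, pos - (genes$end - 1L), 0)))
  as.numeric(d)
}

#' Recursively merge overlapping genesets
#'
#' Repeatedly replaces any pair of genesets meeting the overlap rule by their
#' union until no pair qualifies (a fixed point). The default rule merges A
#' and B when the intersection covers at least `frac_smaller` of the smaller
#' set and at least `frac_larger` of the larger set (defaults 0.8 and 0.5).
#' Candidate pairs are scanned in lexicographic id order and the union keeps
#' the lexicographically smaller id, so the result is deterministic.
#'
#' @param genesets named list of gene-id vectors.
#' @param frac_smaller minimum intersection fraction of the smaller set.
#' @param frac_larger minimum intersection fraction of the larger set.
#' @return list with `genesets` (merged, in lexicographic id order) and
#'   `merge_log` (data.frame of `absorbed_id`, `surviving_id`).
#' @export
merge_genesets <- function(genesets, frac_smaller = 0.8, frac_larger = 0.5) {
  if (!length(genesets)) stop("genesets must be non-empty")
  if (is.null(names(genesets)) || anyDuplicated(names(genesets))) {
    stop("genesets must have unique ids")
  }
  sets <- lapply(genesets, unique)
  sets <- sets[order(names(sets))]
  log_abs <- character(0); log_sur <- character(0)
  repeat {
    ids <- names(sets)
    merged <- FALSE
    n <- length(sets)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          a <- sets[[i]]; b <- sets[[j]]
          ov <- length(intersect(a, b))
          if (ov == 0L) next
          lo <- min(length(a), length(b)); hi <- max(length(a), length(b))
          if (ov >= frac_smaller * lo && ov >= frac_larger * hi) {
            sets[[i]] <- union(a, b)
            log_abs <- c(log_abs, ids[j]); log_sur <- c(log_sur, ids[i])
            sets[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  list(genesets = sets,
       merge_log = data.frame(absorbed_id = log_abs, surviving_id = log_sur,
                              stringsAsFactors = FALSE))
}

#' Build the row-normalized geneset--gene design matrix rho
#'
#' Restricts geneset membership to the selected gene universe and divides
#' each row by its row sum, so each geneset distributes unit mass over its
#' selected member genes. Genesets left empty after restriction are dropped.
#'
#' @param genesets named list (normally the output of [merge_genesets()]).
#' @param selected_genes character vector defining the gene universe and the
#'   column order of rho.
#' @return list with `rho` (genesets x genes, rows sum to 1), `geneset_ids`,
#'   `gene_ids`, `dropped` (ids of emptied genesets).
#' @export
build_rho <- function(genesets, selected_genes) {
  if (is.list(genesets) && !is.null(genesets$genesets)) {
    genesets <- genesets$genesets
  }
  selected_genes <- as.character(selected_genes)
  keep <- lapply(genesets, intersect, selected_genes)
  empty <- names(keep)[lengths(keep) == 0L]
  if (length(empty)) {
    ig_log("build_rho: dropping %d empty geneset(s): %s", length(empty),
           paste(empty, collapse = ", "))
  }
  keep <- keep[lengths(keep) > 0L]
  if (!length(keep)) stop("no geneset retains any selected gene")
  rho <- matrix(0, length(keep), length(selected_genes),
                dimnames = list(names(keep), selected_genes))
  for (s in seq_along(keep)) {
    rho[s, keep[[s]]] <- 1 / length(keep[[s]])
  }
  list(rho = rho, geneset_ids = names(keep), gene_ids = selected_genes,
       dropped = empty)
}

#' Build the gene--CpG interaction graph B
#'
#' For every selected gene, computes the Pearson correlation of its
#' log-expression against each selected CpG within `window` bp, and keeps at
#' most the `top_pairs` smallest-p pairs with p below `p_threshold` as
#' edges. Edge weight is 1 (binary adjacency) by default; `weight = "abs_r"`
#' uses the absolute correlation instead. Constant features yield undefined
#' correlations and are skipped.
#'
#' @param log_expr genes x subjects matrix (selected genes).
#' @param beta CpGs x subjects matrix (selected CpGs).
#' @param layout list with `genes` and `cpgs` data.frames.
#' @param window proximity window in bp (default 500000).
#' @param top_pairs maximum edges per gene (default 10).
#' @param p_threshold correlation significance gate (default 0.05).
#' @param weight `"binary"` or `"abs_r"`.
#' @return list with `B` (sparse genes x CpGs `Matrix`), `edges` (data.frame
#'   `gene_id`, `cpg_id`, `r`, `p_value`, `weight`), `skipped` (constant
#'   features encountered).
#' @export
build_interaction_graph <- function(log_expr, beta, layout,
                                    window = 500000L, top_pairs = 10L,
                                    p_threshold = 0.05,
                                    weight = c("binary", "abs_r")) {
  weight <- match.arg(weight)
  if (ncol(log_expr) != ncol(beta)) {
    stop("log_expr and beta must share the subject axis")
  }
  n <- ncol(log_expr)
  genes <- layout$genes[match(rownames(log_expr), layout$genes$id), ,
                        drop = FALSE]
  cpgs <- layout$cpgs[match(rownames(beta), layout$cpgs$id), , drop = FALSE]
  if (anyNA(genes$id) || anyNA(cpgs$id)) {
    stop("coordinates missing for some features")
  }
  gene_sd <- apply(log_expr, 1L, sd)
  cpg_sd <- apply(beta, 1L, sd)
  skipped <- c(rownames(log_expr)[gene_sd == 0], rownames(beta)[cpg_sd == 0])
  if (length(skipped)) {
    ig_log("build_interaction_graph: %d constant feature(s) skipped",
           length(skipped))
  }
  edges <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    if (gene_sd[g] == 0) next
    d <- ifelse(cpgs$chrom != genes$chrom[g], Inf,
                ifelse(cpgs$start < genes$start[g],
                       genes$start[g] - cpgs$start,
                       ifelse(cpgs$start >= genes$end[g],
                              cpgs$start - (genes$end[g] - 1L), 0)))
    prox <- which(d <= window & cpg_sd > 0)
    if (!length(prox)) next
    r <- as.vector(cor(log_expr[g, ], t(beta[prox, , drop = FALSE])))
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
    keep <- which(p < p_threshold)
    if (!length(keep)) next
    keep <- keep[order(p[keep], rownames(beta)[prox][keep])]
    keep <- keep[seq_len(min(top_pairs, length(keep)))]
    edges[[g]] <- data.frame(gene_id = rownames(log_expr)[g],
                             cpg_id = rownames(beta)[prox][keep],
                             r = r[keep], p_value = p[keep],
                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    edges <- data.frame(gene_id = character(0), cpg_id = character(0),
                        r = numeric(0), p_value = numeric(0),
                        stringsAsFactors = FALSE)
  }
  edges$weight <- if (weight == "binary") rep(1, nrow(edges)) else abs(edges$r)
  B <- Matrix::sparseMatrix(
    i = match(edges$gene_id, rownames(log_expr)),
    j = match(edges$cpg_id, rownames(beta)),
    x = edges$weight,
    dims = c(nrow(log_expr), nrow(beta)),
    dimnames = list(rownames(log_expr), rownames(beta)))
  list(B = B, edges = edges, skipped = skipped)
}

#' Normalize the selected matrices into model-ready inputs
#'
#' Applies, in order: (i) optional covariate correction — per feature, the
#' OLS residual on age and sex plus the feature mean; (ii) clipping at zero
#' (the factorization takes only non-negative input); (iii) division of each
#' feature by its mean; (iv) omic balancing — with `n1` genes and `n2` CpGs,
#' the expression view is multiplied by `n2/(n1+n2)` and the methylation view
#' by `n1/(n1+n2)`, so neither view dominates the joint reconstruction loss
#' by feature count alone. Outputs are transposed to subjects x features.
#'
#' @param expr genes x subjects matrix (selected genes; log scale).
#' @param beta CpGs x subjects matrix (selected CpGs).
#' @param covariates data.frame with `age` and `sex`, one row per subject.
#' @param residualize apply step (i) (default TRUE).
#' @return list with `X1` (subjects x genes), `X2` (subjects x CpGs),
#'   `scale1`, `scale2` (the balancing factors), and `dropped` (zero-mean
#'   features removed).
#' @export
normalize_inputs <- function(expr, beta, covariates = NULL,
                             residualize = !is.null(covariates)) {
  step <- function(M) {
    if (residualize) {
      X <- cbind(1, covariates$age, covariates$sex)
      # residual + feature mean, computed feature-wise in one solve
      bhat <- t(solve(crossprod(X), crossprod(X, t(M))))
      M <- M - bhat %*% t(X) + rowMeans(M)
    }
    M <- pmax(M, 0)
    mu <- rowMeans(M)
    drop <- mu == 0
    ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
    list(M = M[!drop, , drop = FALSE] / mu[!drop], dropped_ids = ids[drop])
  }
  if (residualize && (is.null(covariates) ||
                      !all(c("age", "sex") %in% names(covariates)))) {
    stop("covariates with 'age' and 'sex' required when residualize = TRUE")
  }
  if (residualize && anyNA(covariates[c("age", "sex")])) {
    stop("covariates must be complete")
  }
  e <- step(expr); b <- step(beta)
  dropped <- c(e$dropped_ids, b$dropped_ids)
  if (length(dropped)) {
    ig_log("normalize_inputs: dropped %d zero-mean feature(s)",
           length(dropped))
  }
  n1 <- nrow(e$M); n2 <- nrow(b$M)
  s1 <- n2 / (n1 + n2); s2 <- n1 / (n1 + n2)
  list(X1 = t(e$M * s1), X2 = t(b$M * s2), scale1 = s1, scale2 = s2,
       dropped = dropped)
}

#' Annotate CpGs to genes (body or promoter-proximal)
#'
#' A CpG is annotated to a gene when it lies inside the gene body or within
#' `upstream` bp upstream of the transcription start site, strand-aware: the
#' TSS is `start` on the plus strand and `end - 1` on the minus strand
#' (0-based half-open intervals). Genes with unknown strand fall back to the
#' body-only rule.
#'
#' @param layout list with `genes` (with `strand`) and `cpgs`.
#' @param upstream promoter window in bp (default 1500).
#' @return data.frame `cpg_id`, `gene_id` (one row per annotation).
#' @export
annotate_cpg_to_gene <- function(layout, upstream = 1500L) {
  genes <- layout$genes; cpgs <- layout$cpgs
  unknown <- !(genes$strand %in% c("+", "-"))
  if (any(unknown)) {
    ig_log("annotate_cpg_to_gene: %d gene(s) with unknown strand; body-only rule",
           sum(unknown))
  }
  out <- vector("list", nrow(cpgs))
  for (i in seq_len(nrow(cpgs))) {
    pos <- cpgs$start[i]
    same <- genes$chrom == cpgs$chrom[i]
    body <- same & pos >= genes$start & pos < genes$end
    prom <- same & !unknown & ifelse(
      genes$strand == "+",
      pos < genes$start & genes$start - pos <= upstream,
      pos >= genes$end & pos - (genes$end - 1L) <= upstream)
    hit <- which(body | prom)
    if (length(hit)) {
      out[[i]] <- data.frame(cpg_id = cpgs$id[i], gene_id = genes$id[hit],
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(cpg_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}
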