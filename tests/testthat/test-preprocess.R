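make_layout <- function(genes, cpgs, snps = NULL) {
  if (is.null(snps)) {
    snps <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), id = character(0))
  }
  list(genes = genes, cpgs = cpgs, snps = snps)
}

test_that("row-wise Welch statistics agree with t.test", {
  set.seed(31)
  M <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(paste0("f", 1:20), NULL))
  labels <- rep(c(1, 0), c(14, 16))
  st <- igem:::welch_rows(M, labels)
  for (i in c(1, 7, 20)) {
    tt <- t.test(M[i, labels == 1], M[i, labels == 0])
    expect_equal(st$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(st$t[i], unname(tt$statistic), tolerance = 1e-12)
  }
})

test_that("differential expression gates on p-value and geneset membership", {
  set.seed(32)
  n <- 50
  labels <- rep(c(1, 0), each = n)
  G <- 40
  M <- matrix(rnorm(G * 2 * n), G, 2 * n,
              dimnames = list(sprintf("g%02d", 1:G), NULL))
  planted <- 1:10
  M[planted, labels == 1] <- M[planted, labels == 1] + 2  # 2 SD shift
  gs <- list(set1 = sprintf("g%02d", 1:30))               # g31..g40 outside
  de <- differential_expression(M, labels, gs)
  # planted 2-SD shifts at n=50/50 are essentially always detected
  expect_gte(mean(de$pass[planted]), 0.95)
  # null genes inside the geneset pass at roughly the nominal rate
  expect_lt(mean(de$pass[11:30]), 0.3)
  # strong signal outside every geneset never passes
  M2 <- M; M2[35, labels == 1] <- M2[35, labels == 1] + 5
  de2 <- differential_expression(M2, labels, gs)
  expect_lt(de2$p_value[35], 0.001)
  expect_false(de2$pass[35])
  expect_false(any(de$pass[31:40]))
})

test_that("degenerate and invalid differential inputs are handled", {
  M <- matrix(1, 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  M[2, ] <- rnorm(10)
  labels <- rep(c(1, 0), each = 5)
  expect_warning(de <- differential_expression(M, labels, list(s = c("a", "b", "c"))),
                 "zero within-group variance")
  expect_equal(de$p_value[c(1, 3)], c(1, 1))
  expect_error(differential_expression(M, rep(1, 10), list(s = "a")),
               "both groups")
})

test_that("differential methylation applies the effect and window rules", {
  set.seed(33)
  n <- 50
  labels <- rep(c(1, 0), each = n)
  genes <- data.frame(chrom = "chr1", start = 1000000L, end = 1010000L,
                      id = "gA", strand = "+")
  cpgs <- data.frame(chrom = "chr1",
                     start = c(1200000L, 1200100L, 1700000L, 1200200L),
                     end = c(1200001L, 1200101L, 1700001L, 1200201L),
                     id = c("cg1", "cg2", "cg3", "cg4"))
  base <- matrix(0.5, 4, 2 * n, dimnames = list(cpgs$id, NULL))
  base[1, labels == 1] <- 0.5 + 0.024   # just under the effect threshold
  base[2, labels == 1] <- 0.5 + 0.10    # proximal, clear effect
  base[3, labels == 1] <- 0.5 + 0.10    # 600+ kb away from the gene end
  base[4, labels == 1] <- 0.5 + 0.025   # exactly at the threshold
  # constant-within-group rows trigger the degenerate-variance warning
  expect_warning(
    dm <- differential_methylation(base, labels, "gA",
                                   make_layout(genes, cpgs)),
    "zero within-group variance")
  expect_equal(dm$pass, c(FALSE, TRUE, FALSE, TRUE))
  expect_error(differential_methylation(base * 3, labels, "gA",
                                        make_layout(genes, cpgs)),
               "\\[0, 1\\]")
})

test_that("planted differential CpGs from the generator mostly pass", {
  co <- generate_cohort(sim_config(n_subjects = 100L, n_topics = 3L,
                                   n_genes = 60L, n_cpgs = 80L,
                                   n_snps = 50L, n_genesets = 8L,
                                   diff_frac = 0.25, beta_effect = 0.05),
                        seed = 77)
  dm <- differential_methylation(co$methylation, co$truth$labels,
                                 co$layout$genes$id, co$layout)
  planted <- dm$feature_id %in% co$truth$differential_cpg_ids
  expect_gte(mean(dm$pass[planted]), 0.9)
})

test_that("geneset merging is deterministic, recursive and idempotent", {
  # disjoint sets stay apart
  m <- merge_genesets(list(a = c("g1", "g2"), b = c("g3", "g4")))
  expect_equal(length(m$genesets), 2L)
  expect_equal(nrow(m$merge_log), 0L)
  # identical sets merge under any reading of the rule
  m <- merge_genesets(list(a = c("g1", "g2"), b = c("g1", "g2")))
  expect_equal(names(m$genesets), "a")
  expect_equal(m$merge_log$absorbed_id, "b")
  # a chain A in B in C built to qualify pairwise collapses fully, matching
  # a brute-force fixed-point closure
  A <- paste0("g", 1:8)
  B <- paste0("g", 1:10)    # |A∩B|/|A| = 1, /|B| = 0.8
  C <- paste0("g", 1:12)    # B vs C: 10/10 = 1, 10/12 = 0.83
  chain <- list(C = C, B = B, A = A)
  m <- merge_genesets(chain)
  brute <- function(sets) {
    repeat {
      done <- TRUE
      n <- length(sets)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          ov <- length(intersect(sets[[i]], sets[[j]]))
          lo <- min(lengths(sets[c(i, j)])); hi <- max(lengths(sets[c(i, j)]))
          if (ov >= 0.8 * lo && ov >= 0.5 * hi) {
            sets[[i]] <- union(sets[[i]], sets[[j]])
            sets[[j]] <- NULL; done <- FALSE; break
          }
        }
        if (!done) break
      }
      if (done) return(sets)
    }
  }
  expect_equal(length(m$genesets), length(brute(chain)))
  expect_setequal(m$genesets[[1]], C)
  # idempotent: merging the output changes nothing
  m2 <- merge_genesets(m$genesets)
  expect_equal(m2$genesets, m$genesets)
  expect_equal(nrow(m2$merge_log), 0L)
})

test_that("rho rows are normalized over selected genes", {
  gs <- list(s1 = paste0("g", 1:4), s2 = paste0("g", 5:14),
             s3 = c("gX", "gY"))
  sel <- paste0("g", c(1:4, 9, 10))   # 10-gene s2 keeps exactly 2
  r <- build_rho(gs, sel)
  expect_equal(r$dropped, "s3")
  expect_equal(unname(r$rho["s1", paste0("g", 1:4)]), rep(0.25, 4))
  expect_equal(unname(r$rho["s2", c("g9", "g10")]), rep(0.5, 2))
  expect_equal(unname(rowSums(r$rho)), rep(1, 2), tolerance = 1e-9)
  # property: row sums are 1 on random designs
  set.seed(35)
  genes <- paste0("G", 1:50)
  gs2 <- lapply(1:8, function(i) sample(genes, sample(3:20, 1)))
  names(gs2) <- paste0("S", 1:8)
  r2 <- build_rho(gs2, sample(genes, 30))
  expect_equal(unname(rowSums(r2$rho)), rep(1, nrow(r2$rho)),
               tolerance = 1e-9)
})

test_that("interaction graph keeps at most the top 10 proximal pairs", {
  set.seed(36)
  n <- 40
  genes <- data.frame(chrom = "chr1", start = 500000L, end = 520000L,
                      id = "gA", strand = "+")
  # 15 perfectly correlated proximal CpGs and one distant
  x <- rnorm(n)
  cpgs <- data.frame(chrom = "chr1",
                     start = c(seq(400000L, 680000L, by = 20000L), 5000000L),
                     end = 0L, id = sprintf("cg%02d", 1:16))
  cpgs$end <- cpgs$start + 1L
  expr <- matrix(x, 1, n, dimnames = list("gA", NULL))
  beta <- matrix(rep(plogis(x), 16), 16, n, byrow = TRUE,
                 dimnames = list(cpgs$id, NULL))
  g <- build_interaction_graph(expr, beta, make_layout(genes, cpgs))
  expect_equal(nrow(g$edges), 10L)
  expect_false("cg16" %in% g$edges$cpg_id)
  expect_true(all(g$edges$weight == 1))
  # no proximal CpGs -> no edges
  genes2 <- data.frame(chrom = "chr2", start = 1000L, end = 2000L,
                       id = "gB", strand = "+")
  expr2 <- matrix(x, 1, n, dimnames = list("gB", NULL))
  g2 <- build_interaction_graph(expr2, beta, make_layout(genes2, cpgs))
  expect_equal(nrow(g2$edges), 0L)
})

test_that("interaction graph matches an exhaustive all-pairs oracle", {
  set.seed(37)
  n <- 30; nG <- 6; nC <- 25
  genes <- data.frame(chrom = "chr1",
                      start = as.integer(seq(1e6, 6e6, length.out = nG)),
                      end = 0L, id = sprintf("g%02d", 1:nG), strand = "+")
  genes$end <- genes$start + 10000L
  cpgs <- data.frame(chrom = "chr1",
                     start = as.integer(runif(nC, 5e5, 7e6)), end = 0L,
                     id = sprintf("cg%02d", 1:nC))
  cpgs$end <- cpgs$start + 1L
  expr <- matrix(rnorm(nG * n), nG, n, dimnames = list(genes$id, NULL))
  beta <- matrix(runif(nC * n), nC, n, dimnames = list(cpgs$id, NULL))
  beta[3, ] <- plogis(expr[1, ] + rnorm(n, 0, 0.2))
  lay <- make_layout(genes, cpgs)
  g <- build_interaction_graph(expr, beta, lay, p_threshold = 0.2)
  # oracle: loop every pair, test distance and correlation directly
  oracle <- list()
  for (i in 1:nG) {
    ps <- c(); ids <- c()
    for (j in 1:nC) {
      if (cpgs$chrom[j] != genes$chrom[i]) next
      d <- if (cpgs$start[j] < genes$start[i]) {
        genes$start[i] - cpgs$start[j]
      } else if (cpgs$start[j] >= genes$end[i]) {
        cpgs$start[j] - (genes$end[i] - 1)
      } else 0
      if (d > 500000) next
      p <- cor.test(expr[i, ], beta[j, ])$p.value
      if (p < 0.2) { ps <- c(ps, p); ids <- c(ids, cpgs$id[j]) }
    }
    if (length(ps)) {
      keep <- order(ps, ids)[seq_len(min(10, length(ps)))]
      oracle[[genes$id[i]]] <- sort(ids[keep])
    }
  }
  got <- split(g$edges$cpg_id, g$edges$gene_id)
  expect_equal(lapply(got, sort), oracle[names(got)])
  expect_equal(sort(names(got)), sort(names(oracle)))
  # invariance to CpG row order
  perm <- sample(nC)
  g3 <- build_interaction_graph(expr, beta[perm, ],
                                make_layout(genes, cpgs[perm, ]),
                                p_threshold = 0.2)
  e1 <- g$edges[order(g$edges$gene_id, g$edges$cpg_id), ]
  e2 <- g3$edges[order(g3$edges$gene_id, g3$edges$cpg_id), ]
  rownames(e1) <- rownames(e2) <- NULL
  expect_equal(e1, e2)
})

test_that("input normalization balances the omics as n2/(n1+n2)", {
  set.seed(38)
  n1 <- 30; n2 <- 45; n <- 20
  expr <- matrix(rgamma(n1 * n, 5, 1), n1, n,
                 dimnames = list(paste0("g", 1:n1), paste0("s", 1:n)))
  beta <- matrix(runif(n2 * n, 0.2, 0.8), n2, n,
                 dimnames = list(paste0("c", 1:n2), paste0("s", 1:n)))
  out <- normalize_inputs(expr, beta, residualize = FALSE)
  expect_equal(out$scale1 + out$scale2, 1)
  expect_equal(out$scale1, n2 / (n1 + n2))
  expect_true(all(out$X1 > 0))
  expect_equal(unname(colMeans(out$X1)), rep(n2 / (n1 + n2), n1),
               tolerance = 1e-12)
  expect_equal(unname(colMeans(out$X2)), rep(n1 / (n1 + n2), n2),
               tolerance = 1e-12)
  expect_equal(dim(out$X1), c(n, n1))
  # the cohort-scale arithmetic: 1572 genes and 13900 CpGs
  expect_equal(13900 / (1572 + 13900), 0.8983971, tolerance = 1e-6)
  # covariate residualization keeps non-negativity via clipping
  cov <- data.frame(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5))
  out2 <- normalize_inputs(expr, beta, cov, residualize = TRUE)
  expect_true(all(out2$X1 >= 0) && all(out2$X2 >= 0))
})

test_that("feature selection is invariant to input row order", {
  set.seed(39)
  co <- generate_cohort(tiny_sim_config(diff_frac = 0.2), seed = 12)
  labels <- co$truth$labels
  gs <- co$genesets
  de1 <- differential_expression(log(co$expression), labels, gs)
  perm <- sample(nrow(co$expression))
  de2 <- differential_expression(log(co$expression)[perm, ], labels, gs)
  expect_setequal(de1$feature_id[de1$pass], de2$feature_id[de2$pass])
})

test_that("CpG-to-gene annotation follows the strand-aware promoter rule", {
  genes <- data.frame(chrom = "chr1",
                      start = c(10000L, 50000L),
                      end = c(20000L, 60000L),
                      id = c("plus", "minus"),
                      strand = c("+", "-"))
  cpgs <- data.frame(chrom = "chr1",
                     start = c(9000L,   # 1000 bp upstream of + TSS
                               8400L,   # 1600 bp upstream: out
                               55000L,  # inside - gene body
                               61000L,  # 1001 bp upstream of - TSS (end-1)
                               62000L), # > 1500 bp upstream of - TSS: out
                     end = 0L, id = paste0("cg", 1:5))
  cpgs$end <- cpgs$start + 1L
  ann <- annotate_cpg_to_gene(make_layout(genes, cpgs))
  expect_setequal(ann$cpg_id[ann$gene_id == "plus"], "cg1")
  expect_setequal(ann$cpg_id[ann$gene_id == "minus"], c("cg3", "cg4"))
  # unknown strand: body-only
  genes$strand <- c("?", "?")
  ann2 <- annotate_cpg_to_gene(make_layout(genes, cpgs))
  expect_equal(ann2$cpg_id, "cg3")
})
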