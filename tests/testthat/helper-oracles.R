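# Independent reference implementations used as oracles. These deliberately
# use naive loops / direct formulas, not the package's code paths.

# brute-force Benjamini-Hochberg step-up definition
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  ranked <- p[o] * n / seq_len(n)
  # step-up: adjusted p_(i) = min_{j >= i} ranked_j, capped at 1
  run_min <- rev(cummin(rev(ranked)))
  adj[o] <- pmin(run_min, 1)
  adj
}

# exact HWE p-value by direct enumeration with log-factorials
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- 2 * min(n_AA, n_aa) + n_Aa
  hets <- seq.int(rare %% 2, rare, by = 2)
  logw <- vapply(hets, function(h) {
    a <- (rare - h) / 2
    b <- n - a - h
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) + h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  obs <- w[match(n_Aa, hets)]
  min(1, sum(w[w <= obs * (1 + 1e-9)]))
}

# scalar-loop objective of the factorization (no matrix algebra)
objective_loop_oracle <- function(X1, X2, rho, B, W, alpha, H2,
                                  ln, lw, la, lh) {
  K <- ncol(W); G <- ncol(X1); C <- ncol(X2); S <- nrow(rho); N <- nrow(X1)
  H1 <- matrix(0, K, G)
  for (k in seq_len(K)) for (g in seq_len(G)) {
    for (s in seq_len(S)) H1[k, g] <- H1[k, g] + alpha[k, s] * rho[s, g]
  }
  L <- 0
  for (i in seq_len(N)) for (g in seq_len(G)) {
    r <- X1[i, g] - sum(W[i, ] * H1[, g]); L <- L + r * r
  }
  for (i in seq_len(N)) for (cc in seq_len(C)) {
    r <- X2[i, cc] - sum(W[i, ] * H2[, cc]); L <- L + r * r
  }
  for (g in seq_len(G)) for (cc in seq_len(C)) {
    if (B[g, cc] != 0) {
      L <- L + ln * B[g, cc] * sum((H1[, g] - H2[, cc])^2)
    }
  }
  L + lw * sum(W) + la * sum(alpha) + lh * sum(H2)
}

# standard two-view Lee-Seung multiplicative step (H1 free), reference for
# the reduction property (rho = identity, all penalties zero)
lee_seung_step_oracle <- function(X1, X2, W, H1, H2, eps) {
  W2 <- W * (X1 %*% t(H1) + X2 %*% t(H2)) /
    (W %*% (H1 %*% t(H1) + H2 %*% t(H2)) + eps)
  H1n <- H1 * crossprod(W2, X1) / (crossprod(W2) %*% H1 + eps)
  H2n <- H2 * crossprod(W2, X2) / (crossprod(W2) %*% H2 + eps)
  list(W = W2, H1 = H1n, H2 = H2n)
}

# best mean |Pearson r| over column permutations (exhaustive assignment,
# fine for the K <= 6 used in harnesses)
perm_match_cor <- function(W_true, W_est) {
  K <- ncol(W_true)
  stopifnot(K <= 6)
  cr <- abs(suppressWarnings(cor(W_true, W_est)))
  cr[is.na(cr)] <- 0
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(K))) {
    best <- max(best, mean(cr[cbind(seq_len(K), p)]))
  }
  best
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# small cohort configs reused across tests (overrides win)
tiny_sim_config <- function(...) {
  base <- list(n_subjects = 60L, n_topics = 3L, n_genes = 60L, n_cpgs = 80L,
               n_snps = 100L, n_genesets = 10L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

null_sim_config <- function(...) {
  # no planted structure anywhere: labels, MADRS and genotypes independent
  # of the factors
  base <- list(n_subjects = 60L, n_topics = 5L, n_genes = 24L, n_cpgs = 24L,
               n_snps = 40L, n_genesets = 6L, diff_frac = 0, n_qtl = 0L,
               response_slope = 0, madrs_slope = 0)
  do.call(sim_config, utils::modifyList(base, list(...)))
}
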