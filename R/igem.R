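#' Geneset-embedded joint NMF of expression and methylation
#'
#' Fits the two-view non-negative factorization
#' \deqn{X_1 \approx W H_1, \qquad X_2 \approx W H_2, \qquad H_1 = \alpha \rho,}
#' where `X1` (subjects x genes) and `X2` (subjects x CpGs) share the subject
#' loading matrix `W` (subjects x topics), the gene basis `H1` is constrained
#' to lie in the span of a fixed, row-normalized geneset design `rho`
#' (genesets x genes) through the free topic-geneset score matrix `alpha`
#' (topics x genesets), and the methylation basis `H2` (topics x CpGs) is free.
#' Correlated gene--CpG pairs recorded in the interaction graph `B`
#' (genes x CpGs, non-negative weights) are encouraged to receive similar
#' basis scores through a graph penalty.
#'
#' The objective minimized is
#' \deqn{L = \|X_1 - W\alpha\rho\|_F^2 + \|X_2 - W H_2\|_F^2
#'   + \lambda_{net} \sum_{g,c} B_{gc} \sum_k (H_{1,kg} - H_{2,kc})^2
#'   + \lambda_W \Sigma W + \lambda_\alpha \Sigma \alpha + \lambda_H \Sigma H_2,}
#' with all factors constrained non-negative. Optimization uses blockwise
#' multiplicative updates (order W, alpha, H2; H1 recomputed after the alpha
#' step), which keep every factor non-negative and decrease `L` monotonically
#' in practice; the fit aborts with a diagnostic if any block goes non-finite.
#' With all penalties zero and `rho` the identity, one update step reduces
#' exactly to the standard two-view Lee--Seung rules.
#'
#' Multiple random restarts are run and the restart with the lowest final
#' objective is returned. The fit is deterministic given `seed`.
#'
#' @param X1 numeric matrix, subjects x genes, non-negative.
#' @param X2 numeric matrix, subjects x CpGs, non-negative, same rows as `X1`.
#' @param rho numeric matrix, genesets x genes, non-negative; rows normally
#'   sum to one (see [build_rho()]).
#' @param B numeric matrix (dense or `Matrix` sparse), genes x CpGs,
#'   non-negative interaction weights (see [build_interaction_graph()]).
#' @param K integer, number of topics (latent factors). Default 10.
#' @param lambda_net graph-coupling weight (default 1).
#' @param lambda_W,lambda_alpha,lambda_H L1 sparsity weights on `W`, `alpha`
#'   and `H2` (default 1 each).
#' @param n_restarts number of random restarts (default 1).
#' @param max_iter maximum multiplicative-update iterations per restart
#'   (default 2000).
#' @param rel_tol relative objective-change convergence tolerance
#'   (default 1e-6).
#' @param epsilon denominator guard added to every multiplicative-update
#'   denominator (default 1e-12).
#' @param seed integer seed controlling initialization; `NULL` leaves the RNG
#'   state alone (not reproducible).
#' @param init `"random"` (scaled uniform, default), `"nndsvd"` (SVD-based,
#'   deterministic given the data), or a list with components `W`, `alpha`,
#'   `H2` supplying a starting point.
#' @param verbose print the objective every 50 iterations.
#'
#' @return An object of class `"igem"`: a list with components `W`, `alpha`,
#'   `H2`, `H1` (always `alpha %*% rho`), `objective` (final value),
#'   `objective_trajectory`, `converged`, `iterations`, `restart_objectives`,
#'   and the call/hyperparameters. Dimnames of the inputs are carried through.
#'
#' @seealso [igem_objective()], [igem_rank_scan()], [predict.igem()]
#' @examples
#' sim <- igem_sim_factors(n = 30, n_genes = 40, n_cpgs = 50, n_sets = 6,
#'                         k = 2, seed = 1)
#' fit <- igem(sim$X1, sim$X2, sim$rho, sim$B, K = 2, n_restarts = 2,
#'             lambda_net = 0.1, seed = 1, max_iter = 200)
#' fit
#' @export
igem <- function(X1, X2, rho, B, K = 10,
                 lambda_net = 1, lambda_W = 1, lambda_alpha = 1, lambda_H = 1,
                 n_restarts = 1, max_iter = 2000, rel_tol = 1e-6,
                 epsilon = 1e-12, seed = NULL, init = "random",
                 verbose = FALSE) {
  B <- as.matrix(B)
  ig_stopifnot_matrix(X1, "X1", nonneg = TRUE)
  ig_stopifnot_matrix(X2, "X2", nonneg = TRUE)
  ig_stopifnot_matrix(rho, "rho", nonneg = TRUE)
  ig_stopifnot_matrix(B, "B", nonneg = TRUE)
  N <- nrow(X1); G <- ncol(X1); C <- ncol(X2); S <- nrow(rho)
  if (nrow(X2) != N) stop("X1 and X2 must have the same number of subjects")
  if (ncol(rho) != G) stop("ncol(rho) must match ncol(X1) (genes)")
  if (nrow(B) != G || ncol(B) != C) stop("B must be genes x CpGs")
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K > min(N, G, C)) {
    stop(sprintf("K = %d exceeds min(N, G, C) = %d", K, min(N, G, C)))
  }
  stopifnot(lambda_net >= 0, lambda_W >= 0, lambda_alpha >= 0, lambda_H >= 0,
            rel_tol > 0, max_iter >= 1, n_restarts >= 1)

  hyper <- list(K = K, lambda_net = lambda_net, lambda_W = lambda_W,
                lambda_alpha = lambda_alpha, lambda_H = lambda_H,
                max_iter = as.integer(max_iter), rel_tol = rel_tol,
                epsilon = epsilon, n_restarts = as.integer(n_restarts))

  pre <- ig_precompute(rho, B)
  if (!is.null(seed)) set.seed(as.integer(seed))
  restart_seeds <- if (is.null(seed)) rep(NA_integer_, n_restarts) else
    sample.int(.Machine$integer.max, n_restarts)

  best <- NULL
  restart_obj <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    state <- if (is.list(init)) {
      ig_check_init(init, N, K, S, C)
    } else {
      igem_init(X1, X2, rho, K, method = init, seed = restart_seeds[r])
    }
    run <- ig_iterate(state, X1, X2, rho, B, hyper, pre, verbose = verbose)
    restart_obj[r] <- run$objective
    if (is.null(best) || run$objective < best$objective) best <- run
    if (is.list(init)) break  # a fixed starting point admits no restarts
  }
  if (is.list(init)) restart_obj <- restart_obj[1L]

  ans <- best
  ans$restart_objectives <- restart_obj
  ans$hyper <- hyper
  ans$seed <- seed
  ans$call <- match.call()
  ans$dims <- c(N = N, G = G, C = C, S = S, K = K)
  # carry dimnames through for downstream association tables
  subj <- rownames(X1); genes <- colnames(X1); cpgs <- colnames(X2)
  sets <- rownames(rho)
  topics <- paste0("topic", seq_len(K))
  dimnames(ans$W) <- list(subj, topics)
  dimnames(ans$alpha) <- list(topics, sets)
  dimnames(ans$H1) <- list(topics, genes)
  dimnames(ans$H2) <- list(topics, cpgs)
  class(ans) <- "igem"
  ans
}

# precomputed constants shared by objective and updates
ig_precompute <- function(rho, B) {
  Dg <- rowSums(B)          # gene-side degrees
  Dc <- colSums(B)          # CpG-side degrees
  list(Dg = Dg, Dc = Dc,
       RRt = tcrossprod(rho),                       # rho rho^T   (S x S)
       RDgRt = rho %*% (Dg * t(rho)),               # rho Dg rho^T (S x S)
       BtRt = crossprod(B, t(rho)))                 # B^T rho^T   (C x S)
}

ig_check_init <- function(init, N, K, S, C) {
  stopifnot(is.matrix(init$W), is.matrix(init$alpha), is.matrix(init$H2))
  if (!all(dim(init$W) == c(N, K)) || !all(dim(init$alpha) == c(K, S)) ||
      !all(dim(init$H2) == c(K, C))) {
    stop("init matrices have wrong dimensions")
  }
  if (any(init$W < 0) || any(init$alpha < 0) || any(init$H2 < 0)) {
    stop("init matrices must be non-negative")
  }
  list(W = init$W, alpha = init$alpha, H2 = init$H2)
}

#' Objective value of the geneset-embedded joint factorization
#'
#' Evaluates the penalized squared-error objective (see [igem()]) for an
#' arbitrary non-negative state. Exposed so that diagnostics and tests can
#' evaluate candidate states directly.
#'
#' @inheritParams igem
#' @param W,alpha,H2 the factor blocks (subjects x topics, topics x genesets,
#'   topics x CpGs).
#' @return scalar objective value.
#' @export
igem_objective <- function(X1, X2, rho, B, W, alpha, H2,
                           lambda_net = 1, lambda_W = 1, lambda_alpha = 1,
                           lambda_H = 1) {
  B <- as.matrix(B)
  if (any(W < 0) || any(alpha < 0) || any(H2 < 0)) {
    stop("factors must be non-negative")
  }
  H1 <- alpha %*% rho
  R1 <- X1 - W %*% H1
  R2 <- X2 - W %*% H2
  graph <- 0
  if (lambda_net > 0) {
    Dg <- rowSums(B); Dc <- colSums(B)
    graph <- sum((H1 * H1) %*% Dg) + sum((H2 * H2) %*% Dc) -
      2 * sum((H1 %*% B) * H2)
  }
  sum(R1 * R1) + sum(R2 * R2) + lambda_net * graph +
    lambda_W * sum(W) + lambda_alpha * sum(alpha) + lambda_H * sum(H2)
}

#' One multiplicative-update sweep
#'
#' Applies, in order, the multiplicative updates for `W`, `alpha` and `H2`
#' (with `H1 = alpha %*% rho` refreshed after the `alpha` step), each of the
#' form current value times the ratio of the negative to the positive part of
#' the block gradient, with `epsilon` added to denominators. Non-negativity
#' is preserved exactly.
#'
#' @inheritParams igem_objective
#' @param epsilon denominator guard.
#' @return list with updated `W`, `alpha`, `H2`, `H1`.
#' @export
igem_update_step <- function(X1, X2, rho, B, W, alpha, H2,
                             lambda_net = 1, lambda_W = 1, lambda_alpha = 1,
                             lambda_H = 1, epsilon = 1e-12) {
  B <- as.matrix(B)
  pre <- ig_precompute(rho, B)
  hyper <- list(lambda_net = lambda_net, lambda_W = lambda_W,
                lambda_alpha = lambda_alpha, lambda_H = lambda_H,
                epsilon = epsilon)
  ig_sweep(list(W = W, alpha = alpha, H2 = H2), X1, X2, rho, B, hyper, pre)
}

ig_sweep <- function(state, X1, X2, rho, B, hyper, pre) {
  eps <- hyper$epsilon
  ln <- hyper$lambda_net
  W <- state$W; alpha <- state$alpha; H2 <- state$H2
  H1 <- alpha %*% rho

  num <- X1 %*% t(H1) + X2 %*% t(H2)
  den <- W %*% (tcrossprod(H1) + tcrossprod(H2)) + hyper$lambda_W / 2 + eps
  W <- W * num / den
  ig_check_finite(W, "W")

  WtW <- crossprod(W)
  num <- crossprod(W, X1) %*% t(rho)
  den <- WtW %*% alpha %*% pre$RRt + hyper$lambda_alpha / 2 + eps
  if (ln > 0) {
    num <- num + ln * (H2 %*% pre$BtRt)
    den <- den + ln * (alpha %*% pre$RDgRt)
  }
  alpha <- alpha * num / den
  ig_check_finite(alpha, "alpha")
  H1 <- alpha %*% rho

  num <- crossprod(W, X2)
  den <- WtW %*% H2 + hyper$lambda_H / 2 + eps
  if (ln > 0) {
    num <- num + ln * (H1 %*% B)
    den <- den + ln * sweep(H2, 2, pre$Dc, "*")
  }
  H2 <- H2 * num / den
  ig_check_finite(H2, "H2")

  list(W = W, alpha = alpha, H2 = H2, H1 = H1)
}

ig_check_finite <- function(M, block) {
  if (!all(is.finite(M))) {
    stop(sprintf("non-finite values appeared in factor block '%s' (%d entries); consider a larger epsilon or smaller penalties",
                 block, sum(!is.finite(M))), call. = FALSE)
  }
  invisible(TRUE)
}

ig_iterate <- function(state, X1, X2, rho, B, hyper, pre, verbose = FALSE) {
  obj_fun <- function(s) {
    igem_objective(X1, X2, rho, B, s$W, s$alpha, s$H2,
                   lambda_net = hyper$lambda_net, lambda_W = hyper$lambda_W,
                   lambda_alpha = hyper$lambda_alpha, lambda_H = hyper$lambda_H)
  }
  traj <- numeric(hyper$max_iter + 1L)
  traj[1L] <- obj_fun(state)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(hyper$max_iter)) {
    state <- ig_sweep(state, X1, X2, rho, B, hyper, pre)
    traj[it + 1L] <- obj_fun(state)
    if (verbose && it %% 50L == 0L) {
      message(sprintf("  iter %5d  L = %.6g", it, traj[it + 1L]))
    }
    denom <- max(abs(traj[it]), .Machine$double.eps)
    if (abs(traj[it] - traj[it + 1L]) / denom < hyper$rel_tol) {
      converged <- TRUE
      break
    }
  }
  state$H1 <- state$alpha %*% rho
  list(W = state$W, alpha = state$alpha, H2 = state$H2, H1 = state$H1,
       objective = traj[it + 1L], objective_trajectory = traj[seq_len(it + 1L)],
       converged = converged, iterations = it)
}

#' Initialize the factor blocks
#'
#' `"random"` draws every entry uniform on (0.1, 1.1) and rescales each block
#' so the initial reconstruction matches the data scale: `W` and `H2` are
#' scaled by `sqrt(mean(X)/K)`, and `alpha` additionally divides by the mean
#' column mass of `rho` so that `H1 = alpha %*% rho` lands on the same scale.
#' `"nndsvd"` takes the positive parts of the leading singular vectors of
#' `cbind(X1, X2)` (deterministic given the data); `alpha` is obtained by
#' projecting the gene part onto the row space of `rho` and clipping at zero.
#'
#' @inheritParams igem
#' @param method `"random"` or `"nndsvd"`.
#' @return list with strictly positive `W`, `alpha`, `H2`.
#' @export
igem_init <- function(X1, X2, rho, K, method = c("random", "nndsvd"),
                      seed = NULL) {
  method <- match.arg(method)
  N <- nrow(X1); G <- ncol(X1); C <- ncol(X2); S <- nrow(rho)
  floorv <- 1e-6
  if (method == "random") {
    if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
    mX <- (sum(X1) + sum(X2)) / (length(X1) + length(X2))
    sc <- sqrt(max(mX, .Machine$double.eps) / K)
    cmass <- mean(colSums(rho))
    if (!is.finite(cmass) || cmass <= 0) cmass <- 1
    W <- matrix(runif(N * K, 0.1, 1.1) * sc, N, K)
    alpha <- matrix(runif(K * S, 0.1, 1.1) * sc / cmass, K, S)
    H2 <- matrix(runif(K * C, 0.1, 1.1) * sc, K, C)
  } else {
    sv <- svd(cbind(X1, X2), nu = K, nv = K)
    W <- matrix(0, N, K); H <- matrix(0, K, G + C)
    for (k in seq_len(K)) {
      u <- sv$u[, k]; v <- sv$v[, k]; s <- sv$d[k]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      if (sum(up) * sum(vp) >= sum(un) * sum(vn)) {
        W[, k] <- sqrt(s) * up; H[k, ] <- sqrt(s) * vp
      } else {
        W[, k] <- sqrt(s) * un; H[k, ] <- sqrt(s) * vn
      }
    }
    H1 <- H[, seq_len(G), drop = FALSE]
    H2 <- H[, G + seq_len(C), drop = FALSE]
    # alpha via ridge projection of H1 onto rows of rho, clipped at zero
    RRt <- tcrossprod(rho) + diag(1e-8, S)
    alpha <- pmax(t(solve(RRt, rho %*% t(H1))), 0)
  }
  list(W = pmax(W, floorv), alpha = pmax(alpha, floorv), H2 = pmax(H2, floorv))
}

#' Rank (topic-number) diagnostics
#'
#' Fits the model over a grid of topic counts and summarizes, per K, the best
#' final objective, the relative reconstruction error of each view, and the
#' dispersion of final objectives across restarts. No automatic selection is
#' performed; the table supports an elbow choice.
#'
#' @inheritParams igem
#' @param k_grid integer vector of topic counts to try.
#' @param ... further arguments passed to [igem()].
#' @return data.frame with one row per K: `K`, `objective`, `rel_err1`,
#'   `rel_err2`, `restart_sd`, `converged`.
#' @export
igem_rank_scan <- function(X1, X2, rho, B, k_grid, n_restarts = 3,
                           seed = NULL, ...) {
  stopifnot(length(k_grid) >= 1)
  n1 <- sqrt(sum(X1^2)); n2 <- sqrt(sum(X2^2))
  rows <- lapply(k_grid, function(k) {
    fit <- igem(X1, X2, rho, B, K = k, n_restarts = n_restarts,
                seed = if (is.null(seed)) NULL else seed + k, ...)
    data.frame(K = k,
               objective = fit$objective,
               rel_err1 = sqrt(sum((X1 - fit$W %*% fit$H1)^2)) / n1,
               rel_err2 = sqrt(sum((X2 - fit$W %*% fit$H2)^2)) / n2,
               restart_sd = sd(fit$restart_objectives),
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' @export
print.igem <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Geneset-embedded joint NMF fit\n"))
  cat(sprintf("  %d subjects, %d genes, %d CpGs, %d genesets, K = %d topics\n",
              d["N"], d["G"], d["C"], d["S"], d["K"]))
  cat(sprintf("  objective %.6g after %d iterations (%s; best of %d restart%s)\n",
              x$objective, x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              length(x$restart_objectives),
              if (length(x$restart_objectives) > 1) "s" else ""))
  invisible(x)
}

#' @export
summary.igem <- function(object, ...) {
  # per-topic mass is what one inspects before interpreting topics
  out <- list(
    dims = object$dims,
    objective = object$objective,
    iterations = object$iterations,
    converged = object$converged,
    restart_objectives = object$restart_objectives,
    topic_mass_W = colSums(object$W),
    topic_mass_H1 = rowSums(object$H1),
    topic_mass_H2 = rowSums(object$H2))
  class(out) <- "summary.igem"
  out
}

#' @export
print.summary.igem <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Geneset-embedded joint NMF: %d x (%d + %d), K = %d\n",
              d["N"], d["G"], d["C"], d["K"]))
  cat(sprintf("final objective %.6g (%d iterations, %s)\n", x$objective,
              x$iterations, if (x$converged) "converged" else "not converged"))
  if (length(x$restart_objectives) > 1) {
    cat("restart objectives: ",
        paste(signif(x$restart_objectives, 6), collapse = ", "), "\n")
  }
  cat("topic mass (colSums of W):\n")
  print(signif(x$topic_mass_W, 4))
  invisible(x)
}

#' Extract factor matrices from an igem fit
#'
#' @param object an `"igem"` fit.
#' @param matrix which block to return: subject scores `"W"`, topic-geneset
#'   scores `"alpha"`, gene basis `"H1"`, or CpG basis `"H2"`.
#' @param ... ignored.
#' @return the requested matrix.
#' @export
coef.igem <- function(object, matrix = c("W", "alpha", "H1", "H2"), ...) {
  matrix <- match.arg(matrix)
  object[[matrix]]
}

#' @export
fitted.igem <- function(object, ...) {
  list(X1 = object$W %*% object$H1, X2 = object$W %*% object$H2)
}

#' Residuals of an igem fit
#'
#' @param object an `"igem"` fit.
#' @param X1,X2 the data matrices the model was fitted to.
#' @param ... ignored.
#' @return list of residual matrices `X1 - W H1` and `X2 - W H2`.
#' @export
residuals.igem <- function(object, X1, X2, ...) {
  f <- fitted(object)
  list(X1 = X1 - f$X1, X2 = X2 - f$X2)
}

#' Project new subjects onto fitted topics
#'
#' Holds the bases `H1`, `H2` fixed and solves for non-negative subject
#' loadings of new data by the `W` multiplicative update alone (a fold-in).
#'
#' @param object an `"igem"` fit.
#' @param newX1,newX2 matrices for the new subjects (same genes / CpGs).
#' @param max_iter,rel_tol,seed fold-in iteration controls.
#' @param ... ignored.
#' @return matrix of topic scores, new subjects x K.
#' @export
predict.igem <- function(object, newX1, newX2, max_iter = 500,
                         rel_tol = 1e-8, seed = 1L, ...) {
  stopifnot(ncol(newX1) == ncol(object$H1), ncol(newX2) == ncol(object$H2),
            nrow(newX1) == nrow(newX2))
  H1 <- object$H1; H2 <- object$H2
  K <- object$dims[["K"]]
  set.seed(as.integer(seed))
  mX <- (sum(newX1) + sum(newX2)) / (length(newX1) + length(newX2))
  W <- matrix(runif(nrow(newX1) * K, 0.1, 1.1) * sqrt(max(mX, 1e-12) / K),
              nrow(newX1), K)
  den_const <- tcrossprod(H1) + tcrossprod(H2)
  lW <- object$hyper$lambda_W; eps <- object$hyper$epsilon
  num_const <- newX1 %*% t(H1) + newX2 %*% t(H2)
  prev <- NA_real_
  for (it in seq_len(max_iter)) {
    W <- W * num_const / (W %*% den_const + lW / 2 + eps)
    cur <- sum((newX1 - W %*% H1)^2) + sum((newX2 - W %*% H2)^2) + lW * sum(W)
    if (!is.na(prev) &&
        abs(prev - cur) / max(prev, .Machine$double.eps) < rel_tol) break
    prev <- cur
  }
  colnames(W) <- colnames(object$W)
  rownames(W) <- rownames(newX1)
  W
}

#' Plot the objective trajectory of an igem fit
#'
#' @param x an `"igem"` fit.
#' @param log_scale plot the objective on a log axis (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.igem <- function(x, log_scale = TRUE, ...) {
  y <- x$objective_trajectory
  graphics::plot(seq_along(y) - 1L, y, type = "l",
                 log = if (log_scale) "y" else "",
                 xlab = "iteration", ylab = "objective", ...)
  invisible(x)
}

#' Quick random instance of model-shaped data
#'
#' Draws a small random planted instance (factors, geneset design, sparse
#' interaction graph and the implied data matrices) for examples, harnesses
#' and tests. Not a cohort simulator; see [simulate_cohort()] for that.
#'
#' @param n,n_genes,n_cpgs,n_sets,k dimensions.
#' @param noise_sd additive Gaussian noise SD on the data matrices (clipped
#'   at zero to preserve non-negativity).
#' @param density edge density of the interaction graph.
#' @param seed integer seed.
#' @return list with `X1`, `X2`, `rho`, `B`, and the planted `W`, `alpha`,
#'   `H2`, `H1`.
#' @export
igem_sim_factors <- function(n = 40, n_genes = 60, n_cpgs = 80, n_sets = 8,
                             k = 3, noise_sd = 0, density = 0.02, seed = 1L) {
  set.seed(as.integer(seed))
  W <- matrix(stats::rgamma(n * k, 2, 2), n, k)
  alpha <- matrix(stats::rgamma(k * n_sets, 2, 2), k, n_sets)
  H2 <- matrix(stats::rgamma(k * n_cpgs, 2, 2), k, n_cpgs)
  # geneset design: random membership, every gene in >= 1 set
  memb <- matrix(runif(n_sets * n_genes) < 2 / n_sets, n_sets, n_genes)
  for (g in which(colSums(memb) == 0)) memb[sample.int(n_sets, 1L), g] <- TRUE
  rho <- memb / pmax(rowSums(memb), 1)
  H1 <- alpha %*% rho
  X1 <- W %*% H1
  X2 <- W %*% H2
  if (noise_sd > 0) {
    X1 <- pmax(X1 + matrix(rnorm(length(X1), 0, noise_sd), nrow(X1)), 0)
    X2 <- pmax(X2 + matrix(rnorm(length(X2), 0, noise_sd), nrow(X2)), 0)
  }
  B <- matrix(as.numeric(runif(n_genes * n_cpgs) < density), n_genes, n_cpgs)
  list(X1 = X1, X2 = X2, rho = rho, B = B,
       W = W, alpha = alpha, H2 = H2, H1 = H1)
}
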