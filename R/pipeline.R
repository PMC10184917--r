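#' Run the multi-omic pipeline end to end
#'
#' Chains the stages `simulate` (synthetic cohort to disk), `preprocess`
#' (differential filters, geneset merging, rho and B construction,
#' normalization), `fit` (the geneset-embedded joint factorization),
#' `associate` (topic-phenotype statistics, top features, patient
#' clustering) and `qtl` (genotype QC, response scan, SNP-topic regression,
#' cis-QTL), writing every product as TSV under `config$out_dir` and a
#' `manifest.json` recording output checksums, the configuration hash, the
#' seed and the package version. Outputs are byte-identical across reruns
#' with the same configuration and seed.
#'
#' @param config an `"igem_config"` (see [read_config()]), a list of
#'   overrides, or a path to a YAML file.
#' @param stages subset of stages to run (default: those in the config).
#' @return the manifest, invisibly.
#' @export
igem_run <- function(config = igem_default_config(), stages = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "igem_config")) config <- read_config(config)
  stages <- stages %||% config$stages
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  add <- function(...) written <<- c(written, ...)

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(do.call(sim_config, config$sim), config$seed)
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    add(file.path(config$out_dir, "cohort",
                  c("expression.tsv", "methylation.tsv", "genotypes.raw",
                    "genes.bed", "cpgs.bed", "snps.bed", "genesets.gmt",
                    "phenotypes.tsv", "truth.json")))
  }
  if ("preprocess" %in% stages) add(stage_preprocess(config))
  if ("fit" %in% stages) add(stage_fit(config))
  if ("associate" %in% stages) add(stage_associate(config))
  if ("qtl" %in% stages) add(stage_qtl(config))

  written <- sort(unique(written))
  prefix <- paste0(sub("/+$", "", config$out_dir), "/")
  rel <- ifelse(startsWith(written, prefix),
                substring(written, nchar(prefix) + 1L), written)
  manifest <- list(
    package_version = as.character(packageVersion("igem")),
    seed = config$seed,
    config_hash = ig_hash(unclass(config)[setdiff(names(config), "out_dir")]),
    outputs = setNames(lapply(written, function(f) {
      unname(tools::md5sum(f))
    }), rel))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

ig_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

ig_cohort_paths <- function(config) {
  d <- file.path(config$out_dir, "cohort")
  list(expression = file.path(d, "expression.tsv"),
       methylation = file.path(d, "methylation.tsv"),
       genotypes = file.path(d, "genotypes.raw"),
       genes = file.path(d, "genes.bed"),
       cpgs = file.path(d, "cpgs.bed"),
       snps = file.path(d, "snps.bed"),
       gmt = file.path(d, "genesets.gmt"),
       phenotypes = file.path(d, "phenotypes.tsv"))
}

ig_read_phenotypes <- function(config) {
  p <- ig_cohort_paths(config)$phenotypes
  if (!file.exists(p)) stop("missing input: ", p)
  read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

stage_preprocess <- function(config) {
  paths <- ig_cohort_paths(config)
  for (p in unlist(paths)) if (!file.exists(p)) stop("missing input: ", p)
  expr <- read_matrix(paths$expression)
  beta <- read_matrix(paths$methylation)
  layout <- list(genes = read_layout(paths$genes),
                 cpgs = read_layout(paths$cpgs),
                 snps = read_layout(paths$snps))
  genesets <- read_gmt(paths$gmt)
  pheno <- ig_read_phenotypes(config)
  labels <- pheno$response
  covars <- pheno[, c("age", "sex")]
  log_expr <- log(expr)

  merged <- merge_genesets(genesets)
  de <- differential_expression(log_expr, labels, merged$genesets,
                                p_threshold = config$p_expr)
  sel_genes <- de$feature_id[de$pass]
  dm <- differential_methylation(beta, labels, sel_genes, layout,
                                 delta_threshold = config$delta_beta,
                                 window = config$window,
                                 p_gate = config$methyl_p_gate,
                                 p_threshold = config$p_expr)
  sel_cpgs <- dm$feature_id[dm$pass]
  if (length(sel_genes) < 2L || length(sel_cpgs) < 2L) {
    stop("too few features pass the differential filters")
  }
  rho <- build_rho(merged$genesets, sel_genes)
  graph <- build_interaction_graph(log_expr[sel_genes, , drop = FALSE],
                                   beta[sel_cpgs, , drop = FALSE], layout,
                                   window = config$window,
                                   top_pairs = config$top_pairs,
                                   weight = config$edge_weight)
  norm <- normalize_inputs(log_expr[sel_genes, , drop = FALSE],
                           beta[sel_cpgs, , drop = FALSE], covars,
                           residualize = config$residualize)

  d <- config$out_dir
  f <- list(de = file.path(d, "differential_expression.tsv"),
            dm = file.path(d, "differential_methylation.tsv"),
            rho = file.path(d, "rho.tsv"),
            edges = file.path(d, "B_edges.tsv"),
            x1 = file.path(d, "X1.tsv"),
            x2 = file.path(d, "X2.tsv"))
  write.table(de, f$de, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dm, f$dm, sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(rho$rho, f$rho, "geneset_id")
  write.table(graph$edges, f$edges, sep = "\t", quote = FALSE,
              row.names = FALSE)
  # model-ready matrices stored features x subjects like the raw data
  write_matrix(t(norm$X1), f$x1, "gene_id")
  write_matrix(t(norm$X2), f$x2, "cpg_id")
  unlist(f)
}

ig_read_model_inputs <- function(config) {
  d <- config$out_dir
  for (f in c("X1.tsv", "X2.tsv", "rho.tsv", "B_edges.tsv")) {
    if (!file.exists(file.path(d, f))) {
      stop("missing input: ", file.path(d, f))
    }
  }
  X1 <- read_matrix(file.path(d, "X1.tsv"), orientation = "subjects")
  X2 <- read_matrix(file.path(d, "X2.tsv"), orientation = "subjects")
  rho <- read_matrix(file.path(d, "rho.tsv"))
  edges <- read.table(file.path(d, "B_edges.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  B <- matrix(0, ncol(X1), ncol(X2),
              dimnames = list(colnames(X1), colnames(X2)))
  if (nrow(edges)) {
    B[cbind(match(edges$gene_id, rownames(B)),
            match(edges$cpg_id, colnames(B)))] <- edges$weight
  }
  list(X1 = X1, X2 = X2, rho = rho, B = B)
}

stage_fit <- function(config) {
  inp <- ig_read_model_inputs(config)
  fit <- igem(inp$X1, inp$X2, inp$rho, inp$B, K = config$K,
              lambda_net = config$lambda_net, lambda_W = config$lambda_W,
              lambda_alpha = config$lambda_alpha, lambda_H = config$lambda_H,
              n_restarts = config$n_restarts, max_iter = config$max_iter,
              rel_tol = config$rel_tol, seed = config$seed)
  d <- config$out_dir
  f <- list(W = file.path(d, "W.tsv"), alpha = file.path(d, "alpha.tsv"),
            H1 = file.path(d, "H1.tsv"), H2 = file.path(d, "H2.tsv"),
            obj = file.path(d, "objective.tsv"))
  write_matrix(fit$W, f$W, "subject_id")
  write_matrix(fit$alpha, f$alpha, "topic")
  write_matrix(fit$H1, f$H1, "topic")
  write_matrix(fit$H2, f$H2, "topic")
  write.table(data.frame(iteration = seq_along(fit$objective_trajectory) - 1L,
                         objective = fit$objective_trajectory),
              f$obj, sep = "\t", quote = FALSE, row.names = FALSE)
  unlist(f)
}

stage_associate <- function(config) {
  d <- config$out_dir
  W <- read_matrix(file.path(d, "W.tsv"), orientation = "features")
  H1 <- read_matrix(file.path(d, "H1.tsv"))
  H2 <- read_matrix(file.path(d, "H2.tsv"))
  pheno <- ig_read_phenotypes(config)
  w0 <- as.matrix(pheno[, grep("^madrs_w0_item", names(pheno))])
  w8 <- as.matrix(pheno[, grep("^madrs_w8_item", names(pheno))])
  mad <- madrs_change(w0, w8)

  tra <- topic_response_association(W, pheno$response)
  tma <- topic_madrs_association(W, mad)
  topg <- top_features(H1, n = 10L)
  topc <- top_features(H2, n = 10L)
  expr <- read_matrix(ig_cohort_paths(config)$expression)
  gma <- gene_madrs_association(topg, log(expr), mad)
  sig <- tra$topic[tra$significant]
  cl_cols <- if (length(sig) >= 2L) sig else colnames(W)
  cl <- cluster_patients(W[, cl_cols, drop = FALSE])

  f <- list(tra = file.path(d, "topic_response.tsv"),
            tma = file.path(d, "topic_madrs.tsv"),
            topg = file.path(d, "top_genes.tsv"),
            topc = file.path(d, "top_cpgs.tsv"),
            gma = file.path(d, "gene_madrs.tsv"),
            tree = file.path(d, "patient_tree.nwk"))
  write.table(tra, f$tra, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tma, f$tma, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(topg, f$topg, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(topc, f$topc, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gma, f$gma, sep = "\t", quote = FALSE, row.names = FALSE)
  write_patient_tree(cl, f$tree)
  unlist(f)
}

stage_qtl <- function(config) {
  d <- config$out_dir
  paths <- ig_cohort_paths(config)
  geno <- read_genotypes(paths$genotypes)
  pheno <- ig_read_phenotypes(config)
  covars <- pheno[, c("age", "sex")]
  layout <- list(genes = read_layout(paths$genes),
                 cpgs = read_layout(paths$cpgs),
                 snps = read_layout(paths$snps))

  qc <- snp_qc(geno, hwe_p = config$hwe_p,
               missing_rate = config$missing_rate, maf = config$maf)
  scan <- response_snp_scan(qc$dosage, pheno$response, covars,
                            top_p = config$top_snp_p)
  W <- read_matrix(file.path(d, "W.tsv"), orientation = "features")
  top_snps <- scan$snp_id[scan$top]
  str_add <- snp_str_maj <- NULL
  if (length(top_snps)) {
    ds <- qc$dosage[, top_snps, drop = FALSE]
    str_add <- snp_topic_regression(ds, W, covars, coding = "additive")
    snp_str_maj <- snp_topic_regression(ds, W, covars,
                                        coding = "major_presence")
  }
  topg <- read.table(file.path(d, "top_genes.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  topc <- read.table(file.path(d, "top_cpgs.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expr <- read_matrix(paths$expression)
  beta <- read_matrix(paths$methylation)
  genes <- unique(topg$feature_id)
  cpgs <- unique(topc$feature_id)
  eqtl <- cis_qtl(t(log(expr[genes, , drop = FALSE])), qc$dosage, layout,
                  covars, window = config$window, fdr = config$qtl_fdr)
  mqtl <- cis_qtl(t(beta[cpgs, , drop = FALSE]), qc$dosage, layout,
                  covars, window = config$window, fdr = config$qtl_fdr)

  f <- list(qc = file.path(d, "snp_qc_report.tsv"),
            scan = file.path(d, "response_snp_scan.tsv"),
            eqtl = file.path(d, "cis_eqtl.tsv"),
            mqtl = file.path(d, "cis_mqtl.tsv"))
  write.table(data.frame(criterion = names(qc$report),
                         count = as.integer(qc$report)),
              f$qc, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scan, f$scan, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(eqtl, f$eqtl, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mqtl, f$mqtl, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- unlist(f)
  if (!is.null(str_add)) {
    f1 <- file.path(d, "snp_topic_additive.tsv")
    f2 <- file.path(d, "snp_topic_major_presence.tsv")
    write.table(str_add, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(snp_str_maj, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, f1, f2)
  }
  out
}
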