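#' Read a labeled numeric matrix from TSV
#'
#' Matrices are stored features x subjects on disk (the expression-matrix
#' convention): one header row of subject ids and one leading label column of
#' feature ids. `orientation = "subjects"` transposes on read.
#'
#' @param path TSV file.
#' @param orientation `"features"` (as stored) or `"subjects"`
#'   (subjects x features, the model-ready orientation).
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, orientation = c("features", "subjects")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "#", colClasses = NA,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("no columns in ", path)
  labs <- as.character(df[[1L]])
  if (anyDuplicated(labs)) {
    stop("duplicate row label(s) in ", path, ": ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(m) > 0 && !is.numeric(m)) {
    bad <- which(!apply(df[, -1L, drop = FALSE], 2L,
                        function(col) all(!is.na(suppressWarnings(as.numeric(col))) | is.na(col))))
    stop(sprintf("non-numeric cells in %s (column %s)", path,
                 paste(colnames(df)[-1L][bad], collapse = ", ")))
  }
  storage.mode(m) <- "double"
  rownames(m) <- labs
  if (anyDuplicated(colnames(m))) {
    stop("duplicate column label(s) in ", path)
  }
  if (orientation == "subjects") t(m) else m
}

#' Write a labeled matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @param label_name header for the label column.
#' @export
write_matrix <- function(m, path, label_name = "id") {
  stopifnot(!is.null(colnames(m)))
  labs <- rownames(m)
  if (is.null(labs)) {
    if (nrow(m) > 0) stop("matrix must have row labels")
    labs <- character(0)
  }
  df <- data.frame(labs, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- label_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genesets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Duplicate genes within a set are dropped with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L || !nzchar(parts[1L])) {
      stop(sprintf("malformed GMT line %d in %s (blank set name)", i, path))
    }
    nms[i] <- parts[1L]
    genes <- parts[-c(1L, 2L)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("geneset '%s' lists %d gene(s) more than once; deduplicated",
                      parts[1L], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) stop("duplicate geneset ids in ", path)
  names(sets) <- nms
  sets
}

#' Write genesets to a GMT file
#' @param genesets named list of character vectors.
#' @param path output file.
#' @param description description column (recycled).
#' @export
write_gmt <- function(genesets, path, description = "na") {
  stopifnot(!is.null(names(genesets)), all(nzchar(names(genesets))))
  lines <- vapply(seq_along(genesets), function(i) {
    paste(c(names(genesets)[i], description, genesets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genotype dosage table (PLINK .raw dialect or plain TSV)
#'
#' The PLINK `.raw` dialect is space- or tab-separated with columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP
#' (conventionally named `snp_allele`), dosages coded 0/1/2 with `NA` for
#' missing. A plain TSV with a single `IID` label column is also accepted.
#'
#' @param path input file.
#' @return list of class `"genotype_table"`: `dosage` (subjects x SNPs
#'   integer matrix with NA), `snp_ids`, `subject_ids`, and `counted_allele`
#'   (suffix parsed from PLINK-style column names, NA otherwise).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", "-9"))
  plink_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (all(plink_cols %in% colnames(df)[seq_len(6)])) {
    ids <- as.character(df$IID)
    snp_part <- df[, setdiff(colnames(df), plink_cols), drop = FALSE]
  } else {
    ids <- as.character(df[[1L]])
    snp_part <- df[, -1L, drop = FALSE]
  }
  if (anyDuplicated(ids)) stop("duplicate subject ids in ", path)
  dos <- as.matrix(snp_part)
  storage.mode(dos) <- "double"
  if (any(!dos[!is.na(dos)] %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA in ", path)
  }
  cn <- colnames(snp_part)
  allele <- ifelse(grepl("_[ACGT]$", cn), sub(".*_([ACGT])$", "\\1", cn),
                   NA_character_)
  snp_ids <- sub("_[ACGT]$", "", cn)
  colnames(dos) <- snp_ids
  rownames(dos) <- ids
  structure(list(dosage = dos, snp_ids = snp_ids, subject_ids = ids,
                 counted_allele = allele),
            class = "genotype_table")
}

#' Write a genotype table in the PLINK .raw dialect
#' @param geno a `"genotype_table"` (or plain dosage matrix with dimnames).
#' @param path output file.
#' @param sex optional integer vector (1/2) for the SEX column.
#' @export
write_genotypes <- function(geno, path, sex = NULL) {
  dos <- if (inherits(geno, "genotype_table")) geno$dosage else geno
  allele <- if (inherits(geno, "genotype_table")) geno$counted_allele else NULL
  ids <- rownames(dos)
  cn <- colnames(dos)
  if (!is.null(allele)) {
    cn <- ifelse(is.na(allele), cn, paste0(cn, "_", allele))
  }
  out <- data.frame(FID = ids, IID = ids, PAT = 0L, MAT = 0L,
                    SEX = sex %||% 0L, PHENOTYPE = -9L,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(dos))
  colnames(out) <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE", cn)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a BED-like feature layout file
#'
#' 0-based half-open intervals: columns `chrom`, `start`, `end`, `id`, and
#' optionally `strand`. Point features (CpGs, SNPs) use `end = start + 1`.
#'
#' @param path TSV with header.
#' @return data.frame with the columns above.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "id")
  if (!all(need %in% colnames(df))) {
    stop("layout file must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("duplicate feature ids in ", path)
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("invalid intervals (need 0 <= start < end) in ", path)
  }
  df
}

#' @rdname read_layout
#' @param layout data.frame as returned by [read_layout()].
#' @export
write_layout <- function(layout, path) {
  write.table(layout, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration (YAML)
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#' Defaults are the thresholds the pipeline is designed around: differential
#' p 0.05, |delta beta| 0.025, proximity window 500000 bp, top 10 interaction
#' pairs per gene, HWE p 0.001, missing rate 0.01, MAF 0.05, response-SNP
#' p 1e-4, QTL FDR 0.1, K = 10 topics.
#'
#' @param path YAML file (or a list already in memory).
#' @return list of class `"igem_config"`.
#' @export
read_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  def <- igem_default_config()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(def, user)
  # nested sim block gets the same treatment
  if (!is.null(user$sim)) {
    unknown <- setdiff(names(user$sim), names(def$sim))
    if (length(unknown)) {
      stop("unknown sim config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg$sim <- modifyList(def$sim, user$sim)
  }
  structure(cfg, class = "igem_config")
}

#' @rdname read_config
#' @export
igem_default_config <- function() {
  list(
    out_dir = "igem_run",
    seed = 1L,
    stages = c("simulate", "preprocess", "fit", "associate", "qtl"),
    # preprocessing thresholds
    p_expr = 0.05,
    delta_beta = 0.025,
    methyl_p_gate = FALSE,
    window = 500000L,
    top_pairs = 10L,
    edge_weight = "binary",
    residualize = TRUE,
    # model hyperparameters
    K = 10L,
    lambda_net = 1, lambda_W = 1, lambda_alpha = 1, lambda_H = 1,
    n_restarts = 2L, max_iter = 2000L, rel_tol = 1e-6,
    # genetics thresholds
    hwe_p = 0.001, missing_rate = 0.01, maf = 0.05,
    top_snp_p = 1e-4, qtl_fdr = 0.1,
    sim = unclass(sim_config()))
}
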