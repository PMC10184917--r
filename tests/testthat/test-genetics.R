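test_that("HWE exact test handles null, degenerate and symmetric cases", {
  # near-perfect HWE proportions with a common allele
  expect_gt(hwe_exact_test(49, 42, 9), 0.5)
  # monomorphic SNP
  expect_equal(hwe_exact_test(30, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 25), 1)
  # symmetric in the homozygote classes
  for (cnt in list(c(5, 10, 15), c(0, 4, 26), c(12, 1, 2))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_exact_test(cnt[3], cnt[2], cnt[1]), tolerance = 1e-12)
  }
  # strong heterozygote deficit is rejected
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("HWE exact test matches direct enumeration on moderate tables", {
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(1:30, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1); c <- n - a - b
    expect_equal(hwe_exact_test(a, b, c), hwe_enum_oracle(a, b, c),
                 tolerance = 1e-12)
  }
})

test_that("SNP QC applies the missingness, MAF and HWE gates in order", {
  set.seed(52)
  n <- 200
  ok <- rbinom(n, 2, 0.3)
  low_maf <- rbinom(n, 2, 0.049)            # expected MAF just below 0.05
  low_maf <- c(rep(0, n - 20), rep(1, 18), 0, 0)  # exactly 18/400 = 0.045
  missing2 <- ok; missing2[1:4] <- NA       # 2 percent missing
  hwe_bad <- c(rep(0, 100), rep(2, 100))    # no hets at 50/50
  dos <- cbind(ok = ok, low_maf = low_maf, missing2 = missing2,
               hwe_bad = hwe_bad)
  qc <- snp_qc(dos)
  expect_equal(colnames(qc$dosage), "ok")
  expect_equal(qc$removed$reason[match(c("low_maf", "missing2", "hwe_bad"),
                                       qc$removed$snp_id)],
               c("maf", "missing_rate", "hwe"))
  rep_ <- qc$report
  expect_equal(unname(rep_["input"]),
               unname(rep_["retained"] + rep_["removed_missing"] +
                        rep_["removed_maf"] + rep_["removed_hwe"]))
})

test_that("allele-coding flips leave MAF, HWE and association unchanged", {
  set.seed(53)
  n <- 150
  dos <- cbind(a = rbinom(n, 2, 0.35))
  flipped <- 2 - dos
  colnames(flipped) <- "a"
  qc1 <- snp_qc(dos); qc2 <- snp_qc(flipped)
  expect_equal(qc1$maf, qc2$maf)
  expect_equal(qc1$hwe_p, qc2$hwe_p)
  cov <- data.frame(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.5)
  s1 <- response_snp_scan(qc1$dosage, y, cov)
  s2 <- response_snp_scan(qc2$dosage, y, cov)
  expect_equal(abs(s1$t), abs(s2$t), tolerance = 1e-10)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-10)
})

test_that("planted HWE-violating SNPs are preferentially removed", {
  co <- generate_cohort(sim_config(n_subjects = 300L, n_topics = 2L,
                                   n_genes = 10L, n_cpgs = 10L,
                                   n_snps = 120L, n_genesets = 3L,
                                   n_hwe_violations = 20L,
                                   hwe_inbreeding = 0.6,
                                   missing_rate = 0),
                       seed = 54)
  qc <- snp_qc(co$genotypes)
  bad <- co$truth$hwe_violating_snps
  removed_hwe <- qc$removed$snp_id[qc$removed$reason == "hwe"]
  sens <- mean(bad %in% removed_hwe)
  fpr <- mean(setdiff(colnames(co$genotypes$dosage), bad) %in% removed_hwe)
  expect_gt(sens, 0.5)   # F = 0.6 at n = 300 is usually detected
  expect_lt(fpr, 0.05)
})

test_that("response scan matches lm and is invariant to covariate shifts", {
  set.seed(55)
  n <- 120
  dos <- cbind(s1 = rbinom(n, 2, 0.3), s2 = rbinom(n, 2, 0.4))
  dos[1:3, 2] <- NA
  cov <- data.frame(age = rnorm(n, 40, 12), sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(0.8 * dos[, 1] - 0.8))
  scan <- response_snp_scan(dos, y, cov)
  for (j in 1:2) {
    fit <- summary(lm(y ~ dos[, j] + cov$age + cov$sex))
    expect_equal(scan$beta[j], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(scan$p_value[j], fit$coefficients[2, 4], tolerance = 1e-10)
  }
  cov2 <- cov; cov2$age <- cov2$age + 1000
  scan2 <- response_snp_scan(dos, y, cov2)
  expect_equal(scan$p_value, scan2$p_value, tolerance = 1e-8)
  # constant dosage -> NA
  dos3 <- cbind(dos, mono = rep(1, n))
  scan3 <- response_snp_scan(dos3, y, cov)
  expect_true(is.na(scan3$p_value[3]))
})

test_that("genotype codings target additive versus recessive effects", {
  set.seed(56)
  n <- 400
  cov <- data.frame(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5))
  t_add <- t_maj <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    set.seed(600 + s)
    dos <- cbind(snp = rbinom(n, 2, 0.4))
    W_add <- cbind(t1 = 0.5 * dos[, 1] + rnorm(n))          # dosage-linear
    W_rec <- cbind(t1 = 1.0 * (dos[, 1] == 2) + rnorm(n))   # recessive
    t_add[s, 1] <- abs(snp_topic_regression(dos, W_add, cov, "additive")$t)
    t_add[s, 2] <- abs(snp_topic_regression(dos, W_add, cov,
                                            "major_presence")$t)
    t_maj[s, 1] <- abs(snp_topic_regression(dos, W_rec, cov, "additive")$t)
    t_maj[s, 2] <- abs(snp_topic_regression(dos, W_rec, cov,
                                            "major_presence")$t)
  }
  expect_gt(mean(t_add[, 1]), mean(t_add[, 2]))  # additive wins on linear
  expect_gt(mean(t_maj[, 2]), mean(t_maj[, 1]))  # presence wins on recessive
  # with no heterozygotes the codings coincide
  dos2 <- cbind(s = sample(c(0, 2), n, TRUE))
  W <- cbind(t1 = rnorm(n))
  r1 <- snp_topic_regression(dos2, W, cov, "additive")
  r2 <- snp_topic_regression(dos2, W, cov, "major_presence")
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
})

test_that("cis-QTL tests only SNPs inside the window and matches lm", {
  set.seed(57)
  n <- 90
  genes <- data.frame(chrom = "chr1", start = 1000000L, end = 1050000L,
                      id = "gA", strand = "+")
  snps <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                     start = c(600000L, 1025000L, 1651000L, 1000000L),
                     end = 0L, id = c("near", "inside", "far600kb", "otherchr"))
  snps$end <- snps$start + 1L
  lay <- list(genes = genes, cpgs = NULL, snps = snps)
  dos <- matrix(rbinom(n * 4, 2, 0.3), n, 4,
                dimnames = list(NULL, snps$id))
  cov <- data.frame(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5))
  y <- matrix(0.9 * dos[, "inside"] + rnorm(n), n, 1,
              dimnames = list(NULL, "gA"))
  q <- cis_qtl(y, dos, lay, cov)
  expect_setequal(q$snp_id, c("near", "inside"))
  expect_false("far600kb" %in% q$snp_id)
  expect_false("otherchr" %in% q$snp_id)
  for (i in seq_len(nrow(q))) {
    fit <- summary(lm(y[, 1] ~ dos[, q$snp_id[i]] + cov$age + cov$sex))
    expect_equal(q$p_value[i], fit$coefficients[2, 4], tolerance = 1e-10)
    expect_equal(q$beta[i], fit$coefficients[2, 1], tolerance = 1e-10)
  }
  expect_true(q$significant[q$snp_id == "inside"])
  expect_true(all(q$p_adjusted >= q$p_value - 1e-15))
  # window = NULL tests everything (topic / MADRS mode)
  q2 <- cis_qtl(y, dos, lay, cov, window = NULL)
  expect_equal(nrow(q2), 4L)
})

test_that("planted cis-eQTLs are recovered at FDR 0.1", {
  hits <- 0; total <- 0
  for (s in 1:12) {
    co <- generate_cohort(tiny_sim_config(n_qtl = 2L, qtl_beta = 0.8,
                                          missing_rate = 0),
                          seed = 700 + s)
    qtl_truth <- co$truth$qtl_effects
    gq <- qtl_truth[grepl("^gene", qtl_truth$feature_id), , drop = FALSE]
    if (!nrow(gq)) next
    qc <- snp_qc(co$genotypes)
    feats <- t(log(co$expression[gq$feature_id, , drop = FALSE]))
    q <- cis_qtl(feats, qc$dosage, co$layout, co$truth$covariates)
    for (i in seq_len(nrow(gq))) {
      if (!gq$snp_id[i] %in% colnames(qc$dosage)) next
      total <- total + 1
      hit <- q$significant[q$feature_id == gq$feature_id[i] &
                             q$snp_id == gq$snp_id[i]]
      hits <- hits + as.integer(length(hit) == 1 && hit)
    }
  }
  expect_gt(total, 5)
  expect_gte(hits / total, 0.85)
})
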