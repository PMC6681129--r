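# Pearson scan, Bonferroni control, replication rule, matrix assembly.

test_that("pearson_test matches hand computations", {
  perfect <- pearson_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)
  expect_equal(perfect$n, 3L)

  # r = sqrt(3)/2 at n = 3: t = sqrt(3) on 1 df, two-sided p = 1/3
  res <- pearson_test(c(1, 2, 3), c(1, 2, 2))
  expect_equal(res$r, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)

  anti <- pearson_test(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(anti$r, -1)
  expect_equal(anti$p, 0)

  expect_error(pearson_test(c(1, 2), c(3, 4)), "insufficient")
  expect_error(pearson_test(rep(1, 5), 1:5), "constant")
})

test_that("pearson_test agrees with cor.test and is symmetric", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n)
    y <- 0.4 * x + stats::rnorm(n)
    res <- pearson_test(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    sw <- pearson_test(y, x)
    expect_equal(res[c("r", "p", "n")], sw[c("r", "p", "n")])
  }
})

test_that("pearson r is invariant under positive affine maps and flips sign", {
  set.seed(10)
  x <- stats::rnorm(30)
  y <- 0.5 * x + stats::rnorm(30)
  base <- pearson_test(x, y)
  up <- pearson_test(3.2 * x + 7, y)
  dn <- pearson_test(-2 * x + 1, y)
  expect_equal(up$r, base$r, tolerance = 1e-12)
  expect_equal(up$p, base$p, tolerance = 1e-12)
  expect_equal(dn$r, -base$r, tolerance = 1e-12)
})

test_that("t-formula p-values match permutation p-values", {
  set.seed(14)
  n_perm <- 10000L
  for (i in 1:12) {
    n <- sample(15:30, 1)
    x <- stats::rnorm(n)
    y <- 0.3 * x + stats::rnorm(n)
    res <- pearson_test(x, y)
    perms <- replicate(n_perm, abs(stats::cor(x, sample(y))))
    p_perm <- (sum(perms >= abs(res$r)) + 1) / (n_perm + 1)
    se <- sqrt(p_perm * (1 - p_perm) / n_perm)
    expect_lt(abs(res$p - p_perm), 4 * se + 0.02)
  }
})

test_that("bonferroni_threshold divides alpha over the pair grid", {
  expect_equal(signif(bonferroni_threshold(1116, 113, 0.05), 3), 3.96e-7)
  expect_equal(bonferroni_threshold(1, 1, 0.05), 0.05)
  expect_equal(signif(bonferroni_threshold(50, 113, 0.05), 3), 8.85e-6)
  expect_error(bonferroni_threshold(0, 113), "at least 1")
  expect_error(bonferroni_threshold(10, 10, alpha = 1.2), "alpha")
})

test_that("discovery_scan covers the cartesian grid in glycan-major order", {
  set.seed(17)
  n <- 50
  prot <- matrix(stats::rnorm(n * 2), n, 2,
    dimnames = list(sprintf("s%02d", 1:n), c("P1", "P2")))
  glyc <- matrix(stats::rnorm(n * 2), n, 2,
    dimnames = list(sprintf("s%02d", 1:n), c("G1", "G2")))
  glyc[, "G1"] <- prot[, "P1"]  # a perfect pair
  rec <- discovery_scan(prot, glyc, alpha = 0.05)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$glycan_id, c("G1", "G1", "G2", "G2"))
  expect_equal(rec$protein_id, c("P1", "P2", "P1", "P2"))
  expect_equal(attr(rec, "threshold"), 0.05 / 4)
  strong <- rec[rec$glycan_id == "G1" & rec$protein_id == "P1", ]
  expect_equal(strong$status, "discovered")
  expect_equal(strong$r_disc, 1)
  # per-pair results equal the scalar test
  for (i in seq_len(nrow(rec))) {
    ref <- pearson_test(prot[, rec$protein_id[i]], glyc[, rec$glycan_id[i]])
    expect_equal(rec$r_disc[i], ref$r, tolerance = 1e-12)
    expect_equal(rec$p_disc[i], ref$p, tolerance = 1e-12)
  }
  expect_error(discovery_scan(prot, {
    g2 <- glyc
    rownames(g2) <- paste0("x", seq_len(n))
    g2
  }), "alignment")
})

test_that("discovery_scan handles missing data pairwise", {
  set.seed(18)
  n <- 40
  prot <- matrix(stats::rnorm(n * 2), n, 2,
    dimnames = list(sprintf("s%02d", 1:n), c("P1", "P2")))
  glyc <- matrix(stats::rnorm(n), n, 1,
    dimnames = list(sprintf("s%02d", 1:n), "G1"))
  prot[1:5, "P1"] <- NA
  rec <- discovery_scan(prot, glyc)
  expect_equal(rec$n_disc[rec$protein_id == "P1"], n - 5L)
  expect_equal(rec$n_disc[rec$protein_id == "P2"], n)
  ref <- pearson_test(prot[, "P1"], glyc[, "G1"])
  expect_equal(rec$r_disc[rec$protein_id == "P1"], ref$r, tolerance = 1e-12)
})

test_that("replication labels pairs per the sign-consistent nominal rule", {
  set.seed(23)
  n <- 30
  ids <- sprintf("r%02d", 1:n)
  base <- stats::rnorm(n)
  prot <- matrix(base, n, 1, dimnames = list(ids, "P1"))
  glyc <- cbind(
    Gpos = base + stats::rnorm(n, 0, 0.3),   # strong, same sign
    Gneg = -base + stats::rnorm(n, 0, 0.3),  # strong, opposite sign
    Gnull = stats::rnorm(n)                  # independent
  )
  rownames(glyc) <- ids
  rec <- make_records(data.frame(
    glycan_id = c("Gpos", "Gneg", "Gnull", "Gpos"),
    protein_id = "P1",
    r_disc = c(0.5, 0.5, 0.5, 0.5),
    p_disc = c(1e-8, 1e-8, 1e-8, 0.5),
    n_disc = 344L,
    status = c("discovered", "discovered", "discovered", "not_significant"),
    stringsAsFactors = FALSE
  ))
  out <- replicate_associations(rec, prot, glyc)
  expect_equal(out$status, c("replicated", "conflicting", "not_replicated",
    "not_significant"))
  # not_significant records are never tested in replication
  expect_true(is.na(out$r_rep[4]))
  # replication stats come from the replication cohort's own test
  ref <- pearson_test(prot[, "P1"], glyc[, "Gpos"])
  expect_equal(out$r_rep[1], ref$r, tolerance = 1e-12)
  expect_equal(out$p_rep[1], ref$p, tolerance = 1e-12)
})

test_that("untestable replication pairs fall back to not_replicated", {
  n <- 20
  ids <- sprintf("r%02d", 1:n)
  prot <- matrix(stats::rnorm(n), n, 1, dimnames = list(ids, "P1"))
  glyc <- matrix(rep(1, n), n, 1, dimnames = list(ids, "Gconst"))
  rec <- make_records(data.frame(
    glycan_id = c("Gconst", "Gmissing"), protein_id = "P1",
    r_disc = 0.6, p_disc = 1e-9, n_disc = 344L,
    status = "discovered", stringsAsFactors = FALSE
  ))
  out <- replicate_associations(rec, prot, glyc)
  expect_equal(out$status, c("not_replicated", "not_replicated"))
  expect_equal(out$rep_reason, c("untestable", "feature_missing_in_replication"))
})

test_that("association_matrix holds signed r-squared for replicated pairs", {
  rec <- make_records(data.frame(
    glycan_id = c("G1", "G2", "G3"),
    protein_id = c("P1", "P1", "P2"),
    r_disc = c(-0.69, 0.5, 0.4),
    p_disc = 1e-20, n_disc = 344L,
    status = c("replicated", "replicated", "not_replicated"),
    stringsAsFactors = FALSE
  ))
  m <- association_matrix(rec)
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(m["G1", "P1"], -0.4761)
  expect_equal(m["G2", "P1"], 0.25)
  expect_true(abs(m["G1", "P1"]) <= 1)

  none <- rec
  none$status <- "not_replicated"
  expect_warning(m0 <- association_matrix(none), "empty")
  expect_equal(dim(m0), c(0L, 0L))
})

test_that("consistency report sorts by effect size and scores concordance", {
  rec <- make_records(data.frame(
    glycan_id = paste0("G", 1:3), protein_id = "P1",
    r_disc = c(0.2, -0.6, 0.4), p_disc = 1e-9, n_disc = 344L,
    status = "replicated",
    r_rep = c(0.1, -0.3, 0.2), p_rep = 0.01, n_rep = 46L,
    stringsAsFactors = FALSE
  ))
  rep1 <- consistency_report(rec)
  expect_equal(rep1$glycan_id, c("G2", "G3", "G1"))
  expect_equal(attr(rep1, "concordance"), 1.0)

  # discordant + zero-effect pairs count against concordance
  rec$r_rep <- c(-0.1, 0, 0.2)
  rep2 <- consistency_report(rec)
  expect_equal(attr(rep2, "concordance"), 1 / 3)
})

test_that("sign concordance is near one half under the null", {
  set.seed(31)
  n_pairs <- 200
  rec <- make_records(data.frame(
    glycan_id = paste0("G", seq_len(n_pairs)), protein_id = "P1",
    r_disc = stats::rnorm(n_pairs, 0, 0.1),
    p_disc = stats::runif(n_pairs), n_disc = 344L, status = "discovered",
    r_rep = stats::rnorm(n_pairs, 0, 0.1),
    p_rep = stats::runif(n_pairs), n_rep = 46L,
    stringsAsFactors = FALSE
  ))
  conc <- attr(consistency_report(rec), "concordance")
  expect_gt(conc, 0.4)
  expect_lt(conc, 0.6)
})
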