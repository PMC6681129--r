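# Synthetic cohort generator: determinism, closure, planted-truth propagation.

test_that("identical config and seed give identical cohorts", {
  cfg <- synthetic_config(n_discovery = 25, n_replication = 8,
    n_proteins = 5, n_background_proteins = 3, seed = 77)
  a <- generate_cohorts(cfg)
  b <- generate_cohorts(cfg)
  expect_identical(a$discovery, b$discovery)
  expect_identical(a$replication, b$replication)
  # different seed, different draw
  cfg2 <- synthetic_config(n_discovery = 25, n_replication = 8,
    n_proteins = 5, n_background_proteins = 3, seed = 78)
  expect_false(identical(generate_cohorts(cfg2)$discovery$peaks,
    a$discovery$peaks))
})

test_that("emitted peak compositions close to 100 percent per sample", {
  cfg <- synthetic_config(n_discovery = 30, n_replication = 10,
    n_proteins = 6, n_background_proteins = 4, seed = 3)
  co <- generate_cohorts(cfg)
  expect_equal(unname(rowSums(co$discovery$peaks)), rep(100, 30),
    tolerance = 1e-9)
  expect_equal(unname(rowSums(co$replication$peaks)), rep(100, 10),
    tolerance = 1e-9)
  expect_equal(dim(co$discovery$proteins), c(30L, 6L))
  expect_equal(colnames(co$discovery$peaks), paste0("GP", 1:36))
})

test_that("a noise-free single-protein point-mass glycome is deterministic", {
  prof <- matrix(0, 1, 36, dimnames = list(NULL, paste0("GP", 1:36)))
  prof[1, "GP1"] <- 1
  cfg <- synthetic_config(n_discovery = 10, n_replication = 5,
    n_proteins = 1, n_background_proteins = 0,
    glycoform_profiles = prof, glycan_noise_cv = 0,
    protein_readout_noise_sd = 0, seed = 12)
  co <- generate_cohorts(cfg)
  expect_equal(unname(co$discovery$peaks[, "GP1"]), rep(100, 10))
  expect_equal(unname(rowSums(co$discovery$peaks[, -1])), rep(0, 10))
})

test_that("two disjoint single-peak proteins mix by relative abundance", {
  prof <- matrix(0, 2, 36, dimnames = list(NULL, paste0("GP", 1:36)))
  prof[1, "GP1"] <- 1
  prof[2, "GP24"] <- 1
  cfg <- synthetic_config(n_discovery = 20, n_replication = 5,
    n_proteins = 2, n_background_proteins = 0,
    glycoform_profiles = prof, glycan_noise_cv = 0,
    protein_readout_noise_sd = 0, seed = 9)
  co <- generate_cohorts(cfg)
  a <- exp(co$discovery$proteins)  # noise-free readout = log abundance
  expect_equal(unname(co$discovery$peaks[, "GP1"]),
    unname(100 * a[, "P01"] / (a[, "P01"] + a[, "P02"])), tolerance = 1e-9)
  expect_equal(unname(co$discovery$peaks[, "GP1"] + co$discovery$peaks[, "GP24"]),
    rep(100, 20))
})

test_that("simplex violations in supplied profiles are rejected", {
  prof <- matrix(0.5, 2, 36)
  expect_error(generate_cohorts(synthetic_config(
    n_proteins = 2, n_background_proteins = 0,
    glycoform_profiles = prof, seed = 1)), "simplex")
  expect_error(synthetic_config(n_discovery = 2), "at least 3")
  expect_error(synthetic_config(glycan_noise_cv = -1), "non-negative")
})

test_that("a planted source link induces a positive readout-peak correlation", {
  for (seed in 1:10) {
    cfg <- synthetic_config(n_discovery = 150, n_replication = 5,
      n_proteins = 8, n_background_proteins = 6,
      planted_links = list(planted_link("P01", "GP24")), seed = seed)
    co <- generate_cohorts(cfg)
    r <- stats::cor(co$discovery$proteins[, "P01"],
      co$discovery$peaks[, "GP24"])
    expect_gt(r, 0)
  }
})

test_that("an enzyme link scales its peaks with protein abundance", {
  for (seed in 1:5) {
    cfg <- synthetic_config(n_discovery = 200, n_replication = 5,
      n_proteins = 6, n_background_proteins = 6,
      planted_links = list(planted_link("P02", c("GP29", "GP32"),
        type = "enzyme", gamma = 0.8)),
      seed = seed)
    co <- generate_cohorts(cfg)
    r <- stats::cor(co$discovery$proteins[, "P02"],
      co$discovery$peaks[, "GP29"])
    expect_gt(r, 0)
  }
})

test_that("expected signatures propagate planted peaks through the catalog", {
  cfg <- synthetic_config(
    planted_links = list(planted_link("P01", "GP24")), seed = 4)
  truth <- expected_signatures(cfg)
  pos <- truth[truth$expected_sign == 1, ]
  neg <- truth[truth$expected_sign == -1, ]
  # the primary percent trait of the planted peak and every group trait whose
  # numerator contains it are positive
  expect_true(all(c("PGP24", "PGP97", "PGP102", "PGP105") %in% pos$trait_id))
  expect_true(all(truth$protein_id == "P01"))
  # large disjoint composition groups are compositional complements
  expect_true("PGP76" %in% neg$trait_id)   # neutral structures
  expect_false("PGP24" %in% neg$trait_id)

  # a link that feeds neutral non-M9 peaks depresses the within-neutral
  # share of M9
  cfg2 <- synthetic_config(
    planted_links = list(planted_link("P01", c("GP10", "GP11"))), seed = 4)
  truth2 <- expected_signatures(cfg2)
  expect_true("PGP69" %in% truth2$trait_id[truth2$expected_sign == -1])
  expect_true("PGP75" %in% truth2$trait_id[truth2$expected_sign == 1])

  # no planted links, empty truth
  empty <- expected_signatures(synthetic_config(seed = 4))
  expect_equal(nrow(empty), 0L)
})

test_that("the shared-profile null carries no protein-specific glycan signal", {
  cfg <- synthetic_config(n_discovery = 344, n_replication = 46,
    n_proteins = 10, n_background_proteins = 0, shared_profile = TRUE,
    seed = 19)
  co <- generate_cohorts(cfg)
  traits <- derive_all(co$discovery$peaks)
  prot_s <- inverse_normal_matrix(co$discovery$proteins)
  trait_s <- inverse_normal_matrix(traits)
  rec <- discovery_scan(prot_s, trait_s)
  expect_equal(sum(rec$status == "discovered"), 0L)
})
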