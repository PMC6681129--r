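# Peak normalization, neutral subprofile and the 113-trait derivation engine.

test_that("peak areas normalize to percent of total integrated area", {
  uniform <- stats::setNames(rep(7, 36), peak_ids())
  out <- normalize_peaks(uniform)
  expect_equal(unname(out), rep(100 / 36, 36))
  expect_equal(sum(out), 100)

  two <- stats::setNames(rep(0, 36), peak_ids())
  two["GP1"] <- 3
  two["GP2"] <- 1
  out2 <- normalize_peaks(two)
  expect_equal(unname(out2[c("GP1", "GP2")]), c(75, 25))

  # areas already summing to 100 are unchanged
  prof <- random_profiles(1)[1, ]
  expect_equal(normalize_peaks(prof), prof, tolerance = 1e-12)

  expect_error(normalize_peaks(stats::setNames(rep(0, 36), peak_ids())),
    "degenerate")
  neg <- uniform
  neg["GP5"] <- -1
  expect_error(normalize_peaks(neg), "negative")
  expect_error(normalize_peaks(uniform[-1]), "missing peak")
})

test_that("the neutral subprofile renormalizes over unsialylated peaks", {
  ann <- builtin_peak_annotations()
  prof <- stats::setNames(rep(0, 36), peak_ids())
  # three neutral peaks carry 8/12/20 of the total; the rest is sialylated
  prof[c("GP5", "GP8", "GP18")] <- c(8, 12, 20)
  prof["GP24"] <- 60
  gpn <- neutral_subprofile(prof, ann)
  expect_equal(unname(gpn[c("GP5", "GP8", "GP18")]), c(20, 30, 50))
  expect_equal(sum(gpn), 100)
  # M9 = 8% of total with a 40% neutral total gives an M9 GPn of 20
  prof2 <- prof
  prof2[c("GP5", "GP8", "GP18")] <- c(20, 12, 8)
  expect_equal(unname(neutral_subprofile(prof2, ann)["GP18"]), 20)

  only_one <- stats::setNames(rep(0, 36), peak_ids())
  only_one["GP18"] <- 30
  only_one["GP24"] <- 70
  expect_equal(unname(neutral_subprofile(only_one, ann)["GP18"]), 100)

  all_sial <- stats::setNames(rep(0, 36), peak_ids())
  all_sial["GP24"] <- 100
  expect_error(neutral_subprofile(all_sial, ann), "degenerate")
})

test_that("single-trait evaluation matches hand computations", {
  ann <- builtin_peak_annotations()
  cat113 <- builtin_catalog(ann)

  # trisialylated group: GP24 and GP25 are the only trisialylated mass
  prof <- stats::setNames(rep(0, 36), peak_ids())
  prof[c("GP24", "GP25")] <- c(20, 10)
  prof["GP8"] <- 70
  expect_equal(evaluate_trait(cat113$traits[["PGP97"]], prof, ann), 30)

  # fucosylation of digalactosylated neutral structures: F peaks carry 15,
  # the non-fucosylated digalactosylated neutral peak carries 5
  prof2 <- stats::setNames(rep(0, 36), peak_ids())
  prof2[c("GP10", "GP11")] <- c(10, 5)
  prof2["GP8"] <- 5
  prof2["GP24"] <- 80
  expect_equal(evaluate_trait(cat113$traits[["PGP75"]], prof2, ann), 75)

  # ratio trait: trisialylated vs tetrasialylated tetragalactosylated
  prof3 <- stats::setNames(rep(0, 36), peak_ids())
  prof3[c("GP30", "GP31")] <- 15   # gal4 sial3
  prof3["GP33"] <- 15              # gal4 sial4
  prof3["GP8"] <- 55
  expect_equal(
    evaluate_trait(cat113$traits[["PGP110"]], prof3, ann, catalog = cat113),
    2)
})

test_that("derive_all produces the full 113-column trait matrix", {
  cat113 <- builtin_catalog()
  profs <- random_profiles(5, seed = 42)
  tr <- derive_all(profs, cat113)
  expect_equal(dim(tr), c(5L, 113L))
  expect_equal(sum(attr(tr, "kind") == "primary"), 36L)
  # primary traits are the peak percentages themselves
  expect_equal(unname(tr[, paste0("PGP", 1:36)]), unname(profs),
    tolerance = 1e-12)
  # single sample in, 1 x 113 out
  tr1 <- derive_all(profs[1, ], cat113)
  expect_equal(dim(tr1), c(1L, 113L))
  expect_error(derive_all(profs[0, , drop = FALSE], cat113), "empty")
})

test_that("sialylation-degree group traits partition the composition", {
  profs <- random_profiles(20, seed = 7)
  tr <- derive_all(profs)
  partition <- c("PGP76", "PGP95", "PGP96", "PGP97", "PGP98")
  expect_equal(unname(rowSums(tr[, partition])), rep(100, 20),
    tolerance = 1e-9)
})

test_that("derived traits are invariant to rescaling of raw areas", {
  set.seed(11)
  areas <- matrix(stats::rgamma(3 * 36, 2), 3, 36,
    dimnames = list(paste0("s", 1:3), peak_ids()))
  tr1 <- derive_all(normalize_peak_matrix(areas))
  tr2 <- derive_all(normalize_peak_matrix(areas * 137.5))
  expect_equal(tr1, tr2, tolerance = 1e-12)
})

test_that("zero denominators yield missing values, not infinities", {
  prof <- point_profile(c("GP8", "GP24"))  # no tetrasialylated mass at all
  tr <- derive_all(prof)
  expect_true(is.na(tr[, "PGP88"]))   # trisialylated/tetrasialylated ratio
  expect_true(is.na(tr[, "PGP113"]))  # subfraction of tetragalactosylated
  expect_false(any(is.infinite(tr)))
  expect_false(any(is.nan(tr)))
})

test_that("catalog engine agrees with the brute-force oracle", {
  ann <- builtin_peak_annotations()
  cat113 <- builtin_catalog(ann)
  profs <- random_profiles(150, seed = 3, allow_zero = TRUE)
  tr <- derive_all(profs, cat113, ann)
  for (i in seq_len(nrow(profs))) {
    expected <- oracle_trait_values(as.list(profs[i, ]), cat113, ann)
    got <- tr[i, ]
    expect_equal(is.na(got), is.na(expected))
    ok <- !is.na(expected)
    expect_equal(got[ok], expected[ok], tolerance = 1e-9)
  }
})

test_that("the shipped catalog covers the named traits with their semantics", {
  cat113 <- builtin_catalog()
  counts <- catalog_counts(cat113)
  expect_equal(unname(counts["total"]), 113L)
  expect_equal(unname(counts["primary"]), 36L)
  expect_equal(unname(counts["derived"]), 77L)

  expect_true(matches(parse_structure("A3G3S(3,3,3)3"),
    cat113$traits[["PGP97"]]$numerator_predicate))
  expect_false(matches(parse_structure("A3G3S(3,3)2"),
    cat113$traits[["PGP97"]]$numerator_predicate))
  # the named anchor traits sit at their ids
  expect_match(cat113$traits[["PGP93"]]$name, "core fucosylated")
  expect_match(cat113$traits[["PGP69"]]$name, "M9")
  expect_match(cat113$traits[["PGP65"]]$name, "A2G2")
  expect_match(cat113$traits[["PGP108"]]$name, "bisecting")
  expect_match(cat113$traits[["PGP110"]]$name, "tetragalactosylated")
  expect_equal(cat113$traits[["PGP16"]]$name, "FA2BG2S(3)1 + FA2BG2S(6)1")
  expect_equal(cat113$traits[["PGP11"]]$name, "FA2BG2")
})

test_that("the catalog round-trips through its JSON file format", {
  cat113 <- builtin_catalog()
  path <- withr::local_tempfile(fileext = ".json")
  write_catalog(cat113, path)
  back <- read_catalog(path)
  expect_equal(length(back), 113L)
  validate_catalog(back)
  prof <- random_profiles(3, seed = 5)
  expect_equal(derive_all(prof, back), derive_all(prof, cat113),
    tolerance = 1e-12)
})

test_that("catalog invariants are enforced", {
  cat113 <- builtin_catalog()
  broken <- cat113
  broken$traits[["PGP113"]] <- NULL
  expect_error(validate_catalog(broken), "113")
  dup <- cat113
  dup$traits[[113]]$trait_id <- "PGP1"
  expect_error(validate_catalog(dup), "duplicate")
})
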