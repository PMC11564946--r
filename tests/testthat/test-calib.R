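test_that("stage bounds convert to midpoint +/- half-range priors", {
  # published stage-based calibrations: (older, younger) -> mean +/- sd
  cases <- list(
    list(bounds = c(201.3, 199.3), prior = c(200.3, 1.0)),    # Hettangian
    list(bounds = c(33.9, 28.1), prior = c(31.0, 2.9)),       # Rupelian
    list(bounds = c(23.03, 20.44), prior = c(21.735, 1.295)), # Aquitanian
    list(bounds = c(247.0, 242.0), prior = c(244.5, 2.5))     # Anisian
  )
  for (cs in cases) {
    pr <- prior_from_stage(cs$bounds[1], cs$bounds[2])
    expect_equal(pr$prior_mean, cs$prior[1])
    expect_equal(pr$prior_sd, cs$prior[2])
    # round-trip identity: mean +/- sd recovers the bounds
    expect_equal(pr$prior_mean + pr$prior_sd, cs$bounds[1], tolerance = 1e-12)
    expect_equal(pr$prior_mean - pr$prior_sd, cs$bounds[2], tolerance = 1e-12)
  }
})

test_that("degenerate or inverted stage bounds are rejected with diagnostics", {
  expect_error(prior_from_stage(10.0, 10.0), "zero-width|exceed")
  expect_error(prior_from_stage(28.1, 33.9), "exceed")
  expect_error(prior_from_stage(5, -1), ">= 0")
  expect_error(prior_from_stage(NA, 1), "finite")
})

test_that("directly dated priors pass through with validation", {
  pr <- prior_from_date(98.79, 0.62)
  expect_equal(pr$prior_mean, 98.79)
  expect_equal(pr$prior_sd, 0.62)
  expect_equal(pr$evidence, "fossil_dated")
  pr2 <- prior_from_date(1.55, 0.15, evidence = "geological_event")
  expect_equal(pr2$evidence, "geological_event")
  expect_error(prior_from_date(5.0, -1.0), "non-negative")
  expect_error(prior_from_date(-5.0, 1.0), "positive")
})

test_that("calibration_point enforces its invariants", {
  expect_error(calibration_point("X", character(0), "crown", 10, 1), "non-empty")
  expect_error(calibration_point("X", "A", "tip", 10, 1), "'arg'")
  expect_error(calibration_point("X", "A", "crown", -1, 1), "positive")
  cp <- calibration_point("X", c("A", "B"), "stem", 10, 1,
                          evidence = "geological_event", active = FALSE)
  expect_s3_class(cp, "calibration_point")
  expect_false(cp$active)
})

test_that("the packaged calibration table loads fully, inactive rows included", {
  cals <- load_calibration_table(table2_fixture_path())
  ids <- vapply(cals, `[[`, character(1), "id")
  active <- vapply(cals, `[[`, logical(1), "active")
  expect_length(cals, 22L)
  expect_equal(sum(active), 17L)
  expect_true(all(c("A1", "A2", "A3", "A4", "A5", "A6", "B", "C", "D", "E",
                    "F", "G1", "G2", "H", "Q1-6", "Q7", "Q8-12") %in%
                    ids[active]))
  # superseded and conflicting transcription variants ride along inactive
  expect_true(all(c("C-notapplied", "D-notapplied-1", "D-notapplied-2",
                    "E-methods", "Q7-methods") %in% ids[!active]))
  expect_false(any(duplicated(ids)))
  # spot-check transcribed values
  a2 <- cals[[match("A2", ids)]]
  expect_equal(a2$prior_mean, 200.3)
  expect_equal(a2$prior_sd, 1.0)
  expect_equal(a2$placement, "stem")
})

test_that("load/serialize of the calibration fixture is byte-stable", {
  path <- table2_fixture_path()
  original <- readLines(path)
  once <- write_calibration_table(load_calibration_table(path))
  expect_identical(once, original)
  # and idempotent through a second cycle via a temp file
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(once, tmp)
  expect_identical(write_calibration_table(load_calibration_table(tmp)), once)
})

test_that("malformed calibration tables are rejected row by row", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  header <- "id\tingroup_taxa\tplacement\tprior_mean_ma\tprior_sd_ma\tevidence\tactive"
  writeLines(header, tmp)
  expect_identical(load_calibration_table(tmp), list())

  writeLines(c(header, "X\tA\ttip\t10.0000\t1.0000\tfossil_stage\ttrue"), tmp)
  expect_error(load_calibration_table(tmp), "row 2")

  writeLines(c(header,
               "X\tA\tcrown\t10.0000\t1.0000\tfossil_stage\ttrue",
               "X\tB\tcrown\t11.0000\t1.0000\tfossil_stage\ttrue"), tmp)
  expect_error(load_calibration_table(tmp), "duplicate id 'X'")
})

test_that("calibrated nodes resolve to crown MRCA or its stem parent", {
  tr <- toy_annotated_tree()  # ((A,B),C); tips A=1 B=2 C=3, root=4, (A,B)=5
  crown_ab <- calibration_point("x", c("A", "B"), "crown", 10, 1)
  stem_ab <- calibration_point("x", c("A", "B"), "stem", 10, 1)
  expect_equal(resolve_calibrated_node(tr, crown_ab), 5L)
  expect_equal(resolve_calibrated_node(tr, stem_ab), 4L)
  # single-leaf ingroup: crown is the leaf, stem its parent
  leaf <- calibration_point("x", "A", "crown", 10, 1)
  leaf_stem <- calibration_point("x", "A", "stem", 10, 1)
  expect_equal(resolve_calibrated_node(tr, leaf), 1L)
  expect_equal(resolve_calibrated_node(tr, leaf_stem), 5L)
  # stem of the root clade does not exist
  ac_stem <- calibration_point("x", c("A", "C"), "stem", 10, 1)
  expect_error(resolve_calibrated_node(tr, ac_stem), "root")
  # missing taxa
  bad <- calibration_point("x", c("A", "Z"), "crown", 10, 1)
  expect_error(resolve_calibrated_node(tr, bad), "Z")
})

test_that("crown node is a descendant of the stem node for the same ingroup", {
  cfg <- sim_config(n_taxa = 16, seed = 7, root_age = 40)
  tr <- simulate_yule_tree(cfg)
  phy <- as_phylo(tr)
  for (k in c(2, 3, 5)) {
    taxa <- phy$tip.label[seq_len(k) * 2L]
    crown <- resolve_calibrated_node(tr, calibration_point("x", taxa, "crown", 1, 0))
    mrca_age <- node_ages(tr)[crown]
    st <- tryCatch(
      resolve_calibrated_node(tr, calibration_point("x", taxa, "stem", 1, 0)),
      error = function(e) NA_integer_)
    if (!is.na(st)) {
      expect_true(st %in% phy$edge[phy$edge[, 2] == crown, 1])
      expect_gt(node_ages(tr)[st], mrca_age)
    }
  }
})

test_that("posterior-vs-prior consistency report flags only gross violations", {
  tr <- toy_annotated_tree()  # crown (A,B) age = 1 Ma, root age = 3 Ma
  ok <- calibration_point("ok", c("A", "B"), "crown", 1, 0.5)
  z0 <- check_posterior_vs_prior(tr, ok)
  expect_equal(z0$z, 0)
  expect_equal(z0$status, "ok")
  # posterior age 4 sd younger than the prior mean -> flagged
  young <- calibration_point("young", c("A", "B"), "crown", 3, 0.5)
  zf <- check_posterior_vs_prior(tr, young)
  expect_equal(zf$z, -4)
  expect_equal(zf$status, "flagged")
  # sd = 0 with exact match stays ok
  exact <- calibration_point("exact", c("A", "B"), "crown", 1, 0)
  expect_equal(check_posterior_vs_prior(tr, exact)$status, "ok")
})

test_that("the full fixture against a 5-leaf toy tree degrades to unresolvable", {
  cfg <- sim_config(n_taxa = 5, seed = 3, root_age = 10)
  tr <- simulate_yule_tree(cfg)   # tips t01..t05, none in the fixture
  cals <- load_calibration_table(table2_fixture_path())
  rep <- check_posterior_vs_prior(tr, cals)
  expect_equal(nrow(rep), 17L)    # active rows only
  expect_true(all(rep$status == "unresolvable"))
  expect_true(all(is.na(rep$posterior_age_ma)))
})

test_that("prior sampling is truncated at zero", {
  set.seed(11)
  cp <- calibration_point("q", "A", "crown", 0.5, 1)
  draws <- sample_calibration_prior(cp, 500)
  expect_length(draws, 500)
  expect_true(all(draws >= 0))
})
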