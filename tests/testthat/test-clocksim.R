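test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_taxa = 1), "n_taxa")
  expect_error(sim_config(base_freqs = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  expect_error(sim_config(sigma_ln = -0.1), "sigma_ln")
})

test_that("Yule simulation is reproducible and respects the root-age rescale", {
  cfg <- sim_config(n_taxa = 2, seed = 1, root_age = NULL)
  cherry <- simulate_yule_tree(cfg)
  expect_equal(ape::Ntip(as_phylo(cherry)), 2L)
  expect_gt(max(node_ages(cherry)), 0)

  cfg64 <- sim_config(n_taxa = 64, seed = 6, root_age = 100)
  t1 <- simulate_yule_tree(cfg64)
  t2 <- simulate_yule_tree(cfg64)
  expect_identical(write_annotated_nexus(t1), write_annotated_nexus(t2))
  expect_equal(max(node_ages(t1)), 100, tolerance = 1e-12)
  expect_equal(as_phylo(t1)$Nnode, 63L)
  # a different seed gives a different tree
  t3 <- simulate_yule_tree(sim_config(n_taxa = 64, seed = 7, root_age = 100))
  expect_false(identical(write_annotated_nexus(t1), write_annotated_nexus(t3)))
})

test_that("branch rates follow the deterministic trend when noise is off", {
  cfg <- sim_config(n_taxa = 16, seed = 3, root_age = 50, clock_r0 = 0.02,
                    clock_b = 0, sigma_ln = 0)
  tr <- assign_branch_rates(simulate_yule_tree(cfg), cfg)
  br <- tr$node_data$branch_rate
  expect_true(all(abs(br[!is.na(br)] - 0.02) < 1e-14))

  cfgb <- sim_config(n_taxa = 16, seed = 3, root_age = 50, clock_r0 = 0.02,
                     clock_b = -0.05, sigma_ln = 0)
  trb <- assign_branch_rates(simulate_yule_tree(cfgb), cfgb)
  ages <- node_ages(trb)
  phy <- as_phylo(trb)
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2]
    t_mid <- (ages[phy$edge[e, 1]] + ages[child]) / 2
    expect_equal(trb$node_data$branch_rate[child], 0.02 * exp(-0.05 * t_mid),
                 tolerance = 1e-12)
  }
  # a branch whose midpoint sits at 10 Ma has rate r0 * exp(-0.5)
  expect_equal(0.02 * exp(-0.05 * 10), 0.02 * exp(-0.5))
})

test_that("lognormal branch-rate noise is mean-centered (E[multiplier] = 1)", {
  cfg <- sim_config(n_taxa = 512, seed = 19, root_age = 100, clock_r0 = 0.01,
                    clock_b = 0, sigma_ln = 0.5)
  tr <- assign_branch_rates(simulate_yule_tree(cfg), cfg)
  mult <- tr$node_data$branch_rate / 0.01
  mult <- mult[!is.na(mult)]
  # lognormal(-sigma^2/2, sigma) has mean 1 and SD sqrt(exp(sigma^2) - 1)
  se <- sqrt(exp(0.5^2) - 1) / sqrt(length(mult))
  expect_lt(abs(mean(mult) - 1), 4 * se)
  # and the large-sample identity itself, against a direct Monte-Carlo draw
  set.seed(1234)
  draws <- stats::rlnorm(1e5, meanlog = -0.5^2 / 2, sdlog = 0.5)
  expect_lt(abs(mean(draws) - 1), 0.01)
})

test_that("noiseless node points sit on the trend and refit exactly", {
  cfg <- sim_config(n_taxa = 32, seed = 23, root_age = 120, clock_r0 = 0.0128,
                    clock_b = -0.02, sigma_ln = 0)
  tr <- assign_branch_rates(simulate_yule_tree(cfg), cfg)
  ages <- node_ages(tr)
  phy <- as_phylo(tr)
  # fitting on branch-midpoint points recovers (r0, b) to numerical tolerance
  child <- phy$edge[, 2]
  t_mid <- (ages[phy$edge[, 1]] + ages[child]) / 2
  fit <- fit_exponential(data.frame(age_ma = t_mid,
                                    rate = tr$node_data$branch_rate[child]))
  expect_equal(fit$b, -0.02, tolerance = 1e-10)
  expect_equal(fit$r0, 0.0128, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("exact-integral rate averaging matches the analytic branch mean", {
  cfg <- sim_config(n_taxa = 8, seed = 29, root_age = 40, clock_r0 = 0.01,
                    clock_b = -0.03, sigma_ln = 0, rate_integration = "exact")
  tr <- assign_branch_rates(simulate_yule_tree(cfg), cfg)
  ages <- node_ages(tr)
  phy <- as_phylo(tr)
  for (e in seq_len(nrow(phy$edge))) {
    a_p <- ages[phy$edge[e, 1]]; a_c <- ages[phy$edge[e, 2]]
    expected <- 0.01 * (exp(-0.03 * a_p) - exp(-0.03 * a_c)) /
      (-0.03 * (a_p - a_c))
    expect_equal(tr$node_data$branch_rate[phy$edge[e, 2]], expected,
                 tolerance = 1e-12)
  }
})

test_that("HKY transition probabilities satisfy their exact identities", {
  freqs <- c(0.3, 0.25, 0.15, 0.3)
  # nu = 0 -> identity
  expect_equal(hky_transition_probabilities(4, freqs, 0), diag(4),
               ignore_attr = TRUE, tolerance = 1e-12)
  for (nu in c(0.05, 0.5, 2)) {
    P <- hky_transition_probabilities(4, freqs, nu)
    expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
    # stationarity: pi P = pi
    expect_equal(as.numeric(freqs %*% P), freqs, tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  # kappa = 1 with equal frequencies collapses to Jukes-Cantor
  for (nu in c(0.1, 0.7)) {
    P <- hky_transition_probabilities(1, rep(0.25, 4), nu)
    jc_diag <- 0.25 + 0.75 * exp(-4 * nu / 3)
    jc_off <- 0.25 - 0.25 * exp(-4 * nu / 3)
    expect_equal(unname(diag(P)), rep(jc_diag, 4), tolerance = 1e-12)
    expect_equal(P[1, 2], jc_off, tolerance = 1e-12)
  }
})

test_that("HKY matrices agree with direct matrix exponentiation", {
  skip_if_not_installed("Matrix")
  build_q <- function(kappa, f) {
    bases <- c("A", "C", "G", "T")
    Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
    purine <- c(TRUE, FALSE, TRUE, FALSE)
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      Q[i, j] <- f[j] * if (purine[i] == purine[j]) kappa else 1
    }
    diag(Q) <- -rowSums(Q)
    Q / -sum(f * diag(Q))
  }
  set.seed(55)
  for (rep in 1:5) {
    kappa <- runif(1, 0.5, 12)
    f <- runif(4, 0.1, 1); f <- f / sum(f)
    nu <- runif(1, 0, 1.5)
    P_spec <- hky_transition_probabilities(kappa, f, nu)
    P_expm <- as.matrix(Matrix::expm(build_q(kappa, f) * nu))
    expect_equal(unname(P_spec), unname(P_expm), tolerance = 1e-9)
  }
})

test_that("discrete-Gamma category means have mean one and match phangorn", {
  for (alpha in c(0.2, 0.5, 1, 3)) {
    m <- cicadaclock:::.gamma_category_means(alpha, 4)
    expect_equal(mean(m), 1, tolerance = 1e-9)
    expect_true(all(diff(m) > 0))
  }
  skip_if_not_installed("phangorn")
  expect_equal(cicadaclock:::.gamma_category_means(0.5, 4),
               phangorn::discrete.gamma(0.5, 4), tolerance = 1e-7)
})

test_that("alignments have the configured shape and are seed-reproducible", {
  cfg <- sim_config(n_taxa = 5, seed = 2, root_age = 30, seq_length = 1534)
  tr <- assign_branch_rates(simulate_yule_tree(cfg), cfg)
  aln <- simulate_alignment(tr, cfg)
  expect_equal(dim(aln), c(5L, 1534L))
  expect_true(all(aln %in% c("A", "C", "G", "T")))
  expect_identical(simulate_alignment(tr, cfg), aln)
})

test_that("zero-length branches copy the parent sequence unchanged", {
  txt <- "((A[&branch_rate=0.01]:0,B[&branch_rate=0.01]:1)[&branch_rate=0.01]:1,C[&branch_rate=0.01]:2);"
  tr <- suppressWarnings(parse_annotated_nexus(txt))
  cfg <- sim_config(n_taxa = 3, seed = 4, seq_length = 400)
  aln <- simulate_alignment(tr, cfg)
  # A sits at the end of a zero-length branch from (A,B); its sequence must
  # equal the internal node's, which it can only differ from via that branch
  expect_equal(dim(aln), c(3L, 400L))
  # simulate twice: deterministic, and A differs from B (which has length 1)
  expect_identical(simulate_alignment(tr, cfg), aln)
  expect_gt(sum(aln["A", ] != aln["B", ]), 0)
})

test_that("empirical base frequencies estimate the stationary distribution", {
  freqs <- c(0.30, 0.25, 0.15, 0.30)
  cfg <- sim_config(n_taxa = 2, seed = 12, root_age = 5, clock_r0 = 0.001,
                    base_freqs = freqs, seq_length = 1e5)
  tr <- assign_branch_rates(simulate_yule_tree(cfg), cfg)
  aln <- simulate_alignment(tr, cfg)
  emp <- as.numeric(table(factor(aln, levels = c("A", "C", "G", "T")))) /
    length(aln)
  expect_true(all(abs(emp - freqs) < 0.01))
})

test_that("pairwise divergence grows with path length and tracks small nu", {
  # two tips at increasing depths: p-distance approximately nu for small nu
  for (root_age in c(1, 5, 20)) {
    cfg <- sim_config(n_taxa = 2, seed = 31, root_age = root_age,
                      clock_r0 = 0.005, sigma_ln = 0, gamma_alpha = 1e6,
                      seq_length = 20000)
    tr <- assign_branch_rates(simulate_yule_tree(cfg), cfg)
    aln <- simulate_alignment(tr, cfg)
    p <- mean(aln[1, ] != aln[2, ])
    nu <- 2 * root_age * 0.005
    if (nu < 0.15) expect_equal(p, nu, tolerance = 0.15)
    assign(paste0("p", root_age), p, envir = environment())
  }
  expect_lt(p1, p5)
  expect_lt(p5, p20)
})

test_that("fixture suites are complete and byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- generate_fixture_suite(d1, "constant_clock", seed = 1)
  f2 <- generate_fixture_suite(d2, "constant_clock", seed = 1)
  expect_named(f1, c("tree", "alignment", "truth"))
  expect_true(all(file.exists(f1)))
  expect_identical(readLines(f1[["tree"]]), readLines(f2[["tree"]]))
  expect_identical(readLines(f1[["alignment"]]), readLines(f2[["alignment"]]))
  expect_identical(readLines(f1[["truth"]]), readLines(f2[["truth"]]))
  truth <- jsonlite::read_json(f1[["truth"]])
  expect_equal(truth$clock_r0, 0.01)
  expect_equal(truth$clock_b, 0)
  expect_equal(truth$scenario, "constant_clock")
  # the tree file round-trips through the reader
  tr <- parse_annotated_nexus(readLines(f1[["tree"]]))
  expect_equal(ape::Ntip(as_phylo(tr)), 64L)
})
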