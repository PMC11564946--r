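#' Simulation configuration
#'
#' Bundles and validates the parameters of the generative model used for
#' validation: a Yule (pure-birth) timetree, uncorrelated-lognormal branch
#' rates around an optionally time-dependent mean `r(t) = r0 * exp(b * t)`,
#' and HKY+discrete-Gamma sequence evolution.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Yule speciation rate per Myr.
#' @param root_age Optional target root age in Ma; the tree is rescaled so
#'   the root age equals it exactly.
#' @param clock_r0 Mean substitution rate at age 0, substitutions/site/Myr.
#' @param clock_b Exponential time-dependence coefficient per Myr; 0 gives a
#'   constant mean rate, negative values make rates increase toward the
#'   present.
#' @param sigma_ln Lognormal SD of the multiplicative branch-rate noise;
#'   draws have log-mean `-sigma_ln^2/2` so their expectation is exactly 1
#'   (mean-centered noise).
#' @param kappa HKY transition/transversion rate ratio.
#' @param base_freqs Stationary base frequencies, in A, C, G, T order.
#' @param gamma_alpha Shape of the Gamma among-site rate distribution.
#' @param n_gamma_cats Number of discrete Gamma categories (default 4).
#' @param seq_length Alignment length in sites.
#' @param seed Integer master seed; each simulation stage (topology, rates,
#'   site categories, states) derives its own named stream from it.
#' @param rate_integration `"midpoint"` evaluates the time-dependent mean
#'   rate at the branch temporal midpoint; `"exact"` uses the exact average
#'   of `r0 * exp(b * t)` over the branch interval.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_taxa = 64L, birth_rate = 0.05, root_age = 100,
                       clock_r0 = 0.01, clock_b = 0, sigma_ln = 0.3,
                       kappa = 8, base_freqs = c(0.30, 0.25, 0.15, 0.30),
                       gamma_alpha = 0.5, n_gamma_cats = 4L,
                       seq_length = 1534L, seed = 1L,
                       rate_integration = c("midpoint", "exact")) {
  rate_integration <- match.arg(rate_integration)
  stopifnot(n_taxa >= 2, birth_rate > 0,
            is.null(root_age) || root_age > 0,
            clock_r0 > 0, is.finite(clock_b), sigma_ln >= 0,
            kappa > 0, length(base_freqs) == 4L, all(base_freqs > 0),
            gamma_alpha > 0, n_gamma_cats >= 1L, seq_length >= 1L,
            is.numeric(seed), length(seed) == 1L)
  if (abs(sum(base_freqs) - 1) > 1e-8)
    stop("base_freqs must sum to 1 (got ", sum(base_freqs), ")")
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 root_age = root_age, clock_r0 = clock_r0, clock_b = clock_b,
                 sigma_ln = sigma_ln, kappa = kappa,
                 base_freqs = stats::setNames(base_freqs, c("A", "C", "G", "T")),
                 gamma_alpha = gamma_alpha,
                 n_gamma_cats = as.integer(n_gamma_cats),
                 seq_length = as.integer(seq_length),
                 seed = as.integer(seed),
                 rate_integration = rate_integration),
            class = "sim_config")
}

# One named RNG stream per simulation stage, all derived from the master
# seed; kept below 2^31 - 1 (R seeds are 32-bit integers).
.stage_seed <- function(seed, stage) {
  offset <- c(topology = 1, rates = 2, categories = 3, states = 4)[[stage]]
  as.integer((abs(as.double(seed)) + offset * 1000003) %% 2147483647)
}

#' Simulate a Yule timetree
#'
#' Draws a rooted binary ultrametric tree with `n_taxa` tips under a
#' pure-birth (Yule) process, branch lengths in Myr. When
#' `config$root_age` is set, all node times are rescaled so the root age
#' equals it exactly. No rates are attached yet. Fully reproducible from
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return An [annotated_tree] without rate annotations.
#' @export
simulate_yule_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "topology"))
  phy <- ape::rphylo(config$n_taxa, birth = config$birth_rate, death = 0)
  if (!is.null(config$root_age)) {
    height <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * (config$root_age / height)
  }
  phy$tip.label <- sprintf("t%02d", seq_len(config$n_taxa))
  annotated_tree(phy)
}

#' Assign uncorrelated-lognormal branch rates
#'
#' Gives every branch the rate
#' `r = r0 * exp(b * t_mid) * L`, where `t_mid` is the branch temporal
#' midpoint in Ma (or, with `rate_integration = "exact"`, the deterministic
#' factor is the exact time-average of `r0 * exp(b * t)` over the branch)
#' and `L` is an independent lognormal multiplier with `E[L] = 1`
#' (log-mean `-sigma_ln^2/2`, log-SD `sigma_ln`). Node annotations are
#' written so the tree is directly consumable by [rate_age_points()]:
#' `branch_rate` holds the true rate of the branch subtending each node and
#' `rate_median` the median of the rates of the branches adjacent to the
#' node (three for an internal node, two for the root, one for a tip).
#'
#' @param tree An [annotated_tree] (e.g. from [simulate_yule_tree()]).
#' @param config A [sim_config()].
#' @return The tree with `branch_rate`, `rate_median`, and `posterior`
#'   annotations filled in.
#' @export
assign_branch_rates <- function(tree, config) {
  stopifnot(inherits(tree, "annotated_tree"), inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "rates"))
  phy <- tree$phy
  nd <- tree$node_data
  age <- nd$age_ma
  n_node <- nrow(nd)
  root <- ape::Ntip(phy) + 1L
  parent_of <- integer(n_node)
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]

  det_rate <- function(a_child, a_parent) {
    if (config$clock_b == 0) return(rep(config$clock_r0, length(a_child)))
    if (config$rate_integration == "midpoint") {
      config$clock_r0 * exp(config$clock_b * (a_child + a_parent) / 2)
    } else {
      dt <- a_parent - a_child
      avg <- ifelse(dt > 0,
                    (exp(config$clock_b * a_parent) - exp(config$clock_b * a_child)) /
                      (config$clock_b * dt),
                    exp(config$clock_b * a_child))
      config$clock_r0 * avg
    }
  }

  nonroot <- setdiff(seq_len(n_node), root)
  # deterministic draw order: by node number
  L <- if (config$sigma_ln > 0)
    stats::rlnorm(length(nonroot), meanlog = -config$sigma_ln^2 / 2,
                  sdlog = config$sigma_ln)
  else rep(1, length(nonroot))
  nd$branch_rate[nonroot] <-
    det_rate(age[nonroot], age[parent_of[nonroot]]) * L

  kids_of <- split(phy$edge[, 2L], phy$edge[, 1L])
  nd$rate_median <- vapply(seq_len(n_node), function(v) {
    adj <- nd$branch_rate[c(v, kids_of[[as.character(v)]])]
    adj <- adj[!is.na(adj)]
    if (length(adj) == 0L) NA_real_ else stats::median(adj)
  }, numeric(1))
  nd$posterior[(root):n_node] <- 1
  tree$node_data <- nd
  tree
}

#' HKY transition probability matrix
#'
#' Returns the 4x4 matrix of substitution probabilities `P(nu)` under the
#' HKY model with transition/transversion rate ratio `kappa` and stationary
#' base frequencies `base_freqs`, for a branch of expected length `nu`
#' substitutions per site. The rate matrix is scaled so the mean
#' substitution rate at stationarity is 1, and the solution is computed by
#' spectral decomposition of the reversible generator (exact to machine
#' precision). Rows sum to 1; `base_freqs %*% P = base_freqs`; `nu = 0`
#' yields the identity.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freqs Stationary frequencies in A, C, G, T order.
#' @param nu Expected substitutions per site (>= 0).
#' @return A 4x4 row-stochastic matrix with dimnames A, C, G, T.
#' @export
hky_transition_probabilities <- function(kappa, base_freqs, nu) {
  stopifnot(kappa > 0, length(base_freqs) == 4L, all(base_freqs > 0),
            nu >= 0)
  f <- base_freqs / sum(base_freqs)
  bases <- c("A", "C", "G", "T")
  names(f) <- bases
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  is_transition <- function(i, j)
    (bases[i] %in% c("A", "G") && bases[j] %in% c("A", "G")) ||
    (bases[i] %in% c("C", "T") && bases[j] %in% c("C", "T"))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- f[j] * if (is_transition(i, j)) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))   # mean rate at stationarity
  Q <- Q / mu
  # reversible generator: D^{1/2} Q D^{-1/2} is symmetric
  d <- sqrt(f)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  P <- diag(1 / d) %*% eig$vectors %*% diag(exp(eig$values * nu)) %*%
    t(eig$vectors) %*% diag(d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(bases, bases)
  P
}

# Means of the k discrete Gamma categories (equal-probability bins, shape =
# rate = alpha so the overall mean is 1).
.gamma_category_means <- function(alpha, k) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  k * (stats::pgamma(q[-1L], shape = alpha + 1, rate = alpha) -
         stats::pgamma(q[-(k + 1L)], shape = alpha + 1, rate = alpha))
}

#' Simulate an alignment along a rated tree
#'
#' Evolves nucleotide sequences root-to-tips under HKY with discrete-Gamma
#' among-site rate variation (category means, overall mean 1). Root states
#' are drawn from the stationary base frequencies, so empirical frequencies
#' of the simulated alignment estimate them. Each branch contributes
#' `nu = branch_rate * branch_duration * category_multiplier` expected
#' substitutions per site.
#'
#' @param tree An [annotated_tree] with `branch_rate` annotations (from
#'   [assign_branch_rates()]).
#' @param config A [sim_config()].
#' @return Character matrix of tip sequences (taxa in rows), suitable for
#'   [saturation_table()] or [write_fasta()].
#' @export
simulate_alignment <- function(tree, config) {
  stopifnot(inherits(tree, "annotated_tree"), inherits(config, "sim_config"))
  nd <- tree$node_data
  if (all(is.na(nd$branch_rate)))
    stop("tree has no branch rates; run assign_branch_rates() first")
  phy <- tree$phy
  n <- ape::Ntip(phy)
  L <- config$seq_length
  bases <- c("A", "C", "G", "T")
  k <- config$n_gamma_cats
  cat_mult <- .gamma_category_means(config$gamma_alpha, k)

  set.seed(.stage_seed(config$seed, "categories"))
  site_cat <- sample.int(k, L, replace = TRUE)
  set.seed(.stage_seed(config$seed, "states"))
  seqs <- vector("list", n + phy$Nnode)
  root <- n + 1L
  seqs[[root]] <- sample.int(4L, L, replace = TRUE, prob = config$base_freqs)

  # cladewise edge order: parents are always simulated before children
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
    dur <- phy$edge.length[e]
    nu0 <- nd$branch_rate[child] * dur
    parent_seq <- seqs[[par]]
    child_seq <- parent_seq
    if (nu0 > 0) {
      for (g in seq_len(k)) {
        P <- hky_transition_probabilities(config$kappa, config$base_freqs,
                                          nu0 * cat_mult[g])
        for (a in 1:4) {
          idx <- which(parent_seq == a & site_cat == g)
          if (length(idx) > 0L)
            child_seq[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                         prob = P[a, ])
        }
      }
    }
    seqs[[child]] <- child_seq
  }

  out <- matrix("", nrow = n, ncol = L,
                dimnames = list(phy$tip.label, NULL))
  for (tip in seq_len(n)) out[tip, ] <- bases[seqs[[tip]]]
  out
}

#' Write sequences as FASTA
#'
#' @param alignment Character matrix (taxa in rows) or named vector of
#'   sequence strings.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(alignment, path) {
  if (is.matrix(alignment)) {
    seqs <- apply(alignment, 1L, paste, collapse = "")
  } else seqs <- alignment
  stopifnot(!is.null(names(seqs)))
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}

.scenario_config <- function(scenario, seed) {
  switch(scenario,
    constant_clock = sim_config(n_taxa = 64L, birth_rate = 0.05,
                                root_age = 100, clock_r0 = 0.01, clock_b = 0,
                                sigma_ln = 0.3, seed = seed),
    accelerating_clock = sim_config(n_taxa = 64L, birth_rate = 0.05,
                                    root_age = 250, clock_r0 = 0.0128,
                                    clock_b = -0.02, sigma_ln = 0.3,
                                    seed = seed),
    deep_saturation = sim_config(n_taxa = 32L, birth_rate = 0.05,
                                 root_age = 250, clock_r0 = 0.0128,
                                 clock_b = 0, sigma_ln = 0.3, seed = seed),
    stop("unknown scenario '", scenario, "'")
  )
}

#' Generate a named fixture scenario
#'
#' Writes a complete synthetic dataset — annotated NEXUS tree, FASTA
#' alignment, and a truth JSON recording every generating parameter — for
#' one of three standard scenarios:
#'
#' * `constant_clock`: 64 taxa, 100-Myr tree, constant mean rate
#'   0.01 s/s/Myr (`b = 0`);
#' * `accelerating_clock`: 64 taxa, 250-Myr tree, `r0 = 0.0128` s/s/Myr and
#'   `b = -0.02`/Myr, i.e. rates increasing exponentially toward the
#'   present at a COI-like parameter scale;
#' * `deep_saturation`: 32 taxa, 250-Myr tree at a constant COI-like rate
#'   (0.0128 s/s/Myr), deep enough that transition counts saturate.
#'
#' Identical seed and scenario give byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param scenario Scenario name.
#' @param seed Master seed.
#' @return Invisibly, a named character vector of the files written
#'   (`tree`, `alignment`, `truth`).
#' @export
generate_fixture_suite <- function(out_dir,
                                   scenario = c("constant_clock",
                                                "accelerating_clock",
                                                "deep_saturation"),
                                   seed = 1L) {
  scenario <- match.arg(scenario)
  config <- .scenario_config(scenario, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- assign_branch_rates(simulate_yule_tree(config), config)
  aln <- simulate_alignment(tree, config)

  tree_path <- file.path(out_dir, paste0(scenario, "_tree.nex"))
  write_annotated_nexus(tree, tree_path)
  fasta_path <- file.path(out_dir, paste0(scenario, "_alignment.fasta"))
  write_fasta(aln, fasta_path)
  truth_path <- file.path(out_dir, paste0(scenario, "_truth.json"))
  truth <- unclass(config)
  truth$base_freqs <- as.list(truth$base_freqs)
  truth$scenario <- scenario
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(tree = tree_path, alignment = fasta_path, truth = truth_path))
}
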