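test_that("codon_rate_matrix has generator structure", {
  Q <- codon_rate_matrix(2.5, 0.4)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  pi <- attr(Q, "pi")
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)

  # kappa = 1, omega = 1, equal frequencies: all neighbour rates equal
  Q1 <- codon_rate_matrix(1, 1)
  expect_equal(Q1["TTT", "TTC"], Q1["TTT", "TTA"])
  expect_equal(Q1["TTT", "TTC"], Q1["TTT", "CTT"])

  # omega = 0 kills every nonsynonymous rate
  Q0 <- codon_rate_matrix(2, 0)
  expect_identical(unname(Q0["TTT", "TTA"]), 0)   # Phe -> Leu
  expect_gt(Q0["TTT", "TTC"], 0)                  # Phe -> Phe

  # codons differing at >1 position never exchange directly
  expect_identical(unname(Q["TTT", "AAT"]), 0)

  expect_error(codon_rate_matrix(0, 0.5), "kappa")
  expect_error(codon_rate_matrix(-1, 0.5), "kappa")
})

test_that("transition_matrix is stochastic, reversible and matches expm", {
  Q <- codon_rate_matrix(2, 0.3)
  pi <- attr(Q, "pi")

  expect_equal(transition_matrix(Q, 0), diag(61), tolerance = 1e-8,
               ignore_attr = TRUE)
  P <- transition_matrix(Q, 0.7)
  expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10, ignore_attr = TRUE)

  # detailed balance of the reversible construction
  P3 <- transition_matrix(Q, 0.3)
  imbalance <- outer(pi, rep(1, 61)) * P3 - t(outer(pi, rep(1, 61)) * P3)
  expect_lt(max(abs(imbalance)), 1e-10)

  skip_if_not_installed("Matrix")
  Pexp <- as.matrix(Matrix::expm(Matrix::Matrix(unclass(Q) * 0.7)))
  expect_equal(unclass(P), Pexp, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(transition_matrix(Q, -0.1), ">= 0")
})

test_that("compiled pruning matches closed forms and brute force", {
  # single sequence: log stationary frequency of each codon
  m <- codon_model(2, data.frame(prop = 1, omega = 0.5))
  one <- codon_alignment(c(solo = "ATGGCT"), check_stops = FALSE)
  ll1 <- site_log_likelihoods(one, NULL, m)
  idx <- match(c("ATG", "GCT"), sense_codons())
  expect_equal(ll1$site_loglik, log(m$codon_freqs[idx]))

  # two taxa: direct sum over the root state
  two_tree <- ape::read.tree(text = "(x:0.2,y:0.5);")
  pair <- codon_alignment(c(x = "ATGGCTCTT", y = "ATGGCACTC"),
                          check_stops = FALSE)
  ll2 <- site_log_likelihoods(pair, two_tree, m)
  Q <- codon_rate_matrix(m$kappa, 0.5, m$codon_freqs)
  Px <- transition_matrix(Q, 0.2); Py <- transition_matrix(Q, 0.5)
  xs <- match(pair$codons["x", ], sense_codons())
  ys <- match(pair$codons["y", ], sense_codons())
  direct <- vapply(1:3, function(h) {
    log(sum(m$codon_freqs * Px[, xs[h]] * Py[, ys[h]]))
  }, numeric(1))
  expect_equal(ll2$site_loglik, direct, tolerance = 1e-10)

  # four taxa: brute-force enumeration over both internal states
  tr4 <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,C:0.4,D:0.1);")
  m4 <- codon_model(1.8, data.frame(prop = 1, omega = 0.4))
  sim4 <- simulate_codon_alignment(tr4, m4, 10, seed = 3)
  ll4 <- site_log_likelihoods(sim4$alignment, tr4, m4)
  Q4 <- codon_rate_matrix(1.8, 0.4, m4$codon_freqs)
  PA <- transition_matrix(Q4, 0.2); PB <- transition_matrix(Q4, 0.3)
  PI <- transition_matrix(Q4, 0.15)
  PC <- transition_matrix(Q4, 0.4); PD <- transition_matrix(Q4, 0.1)
  st <- function(id) match(sim4$alignment$codons[id, ], sense_codons())
  A <- st("A"); B <- st("B"); C <- st("C"); D <- st("D")
  brute <- vapply(1:10, function(h) {
    inner <- PI %*% (PA[, A[h]] * PB[, B[h]])
    log(sum(m4$codon_freqs * PC[, C[h]] * PD[, D[h]] * inner))
  }, numeric(1))
  expect_lt(max(abs(brute - ll4$site_loglik)), 1e-8)

  # mixture likelihood: explicit class sum
  mix <- codon_model(1.8, data.frame(prop = c(0.6, 0.4), omega = c(0.1, 2)))
  llm <- site_log_likelihoods(sim4$alignment, tr4, mix)
  per_class <- sapply(c(0.1, 2), function(om) {
    site_log_likelihoods(sim4$alignment, tr4,
                         codon_model(1.8, data.frame(prop = 1, omega = om),
                                     mix$codon_freqs))$site_loglik
  })
  by_hand <- log(0.6 * exp(per_class[, 1]) + 0.4 * exp(per_class[, 2]))
  expect_equal(llm$site_loglik, by_hand, tolerance = 1e-10)

  # tree/alignment mismatch reports the symmetric difference
  bad <- codon_alignment(c(A = "ATG", B = "ATG", C = "ATG", E = "ATG"),
                         check_stops = FALSE)
  expect_error(site_log_likelihoods(bad, tr4, m4), "only in tree.*D")
})

test_that("fit_site_model respects nesting and degenerate data", {
  m <- codon_model(2, data.frame(prop = 1, omega = 0.3))
  sim <- simulate_codon_alignment(tree6(), m, 80, seed = 31)
  st <- list(n_starts = 1)
  f0 <- fit_site_model(sim$alignment, tree6(), "M0", settings = st)
  f3 <- fit_site_model(sim$alignment, tree6(), "M3",
                       settings = c(st, list(init_fit = f0)))
  f7 <- fit_site_model(sim$alignment, tree6(), "M7", settings = st)
  f8 <- fit_site_model(sim$alignment, tree6(), "M8",
                       settings = c(st, list(init_fit = f7)))
  expect_gte(f3$lnL, f0$lnL - 1e-4)
  expect_gte(f8$lnL, f7$lnL - 1e-4)
  expect_identical(f3$n_params - f0$n_params, 4L)
  expect_identical(f8$n_params - f7$n_params, 2L)
  # posterior rows sum to 1
  expect_equal(rowSums(f3$site_posteriors), rep(1, 80), tolerance = 1e-9)
  expect_equal(rowSums(f8$site_posteriors), rep(1, 80), tolerance = 1e-9)

  # identical sequences: branch lengths collapse, lnL = sum log pi
  const <- codon_alignment(setNames(rep(strrep("ATGGCTCTTAAG", 5), 6),
                                    paste0("t", 1:6)), check_stops = FALSE)
  fc <- fit_site_model(const, tree6(), "M0", settings = st)
  expect_true(all(fc$tree$edge.length <= 1e-4))
  idx <- match(const$codons[1, ], sense_codons())
  expect_equal(fc$lnL, sum(log(fc$codon_freqs[idx])), tolerance = 1e-3)

  expect_error(fit_site_model(sim$alignment, tree6(), "M0",
                              settings = list(bogus = 1)), "unknown settings")
})

test_that("likelihood_ratio_test computes 2dl, df and p", {
  fake <- function(name, lnL, n_params) {
    structure(list(model_name = name, lnL = lnL, n_params = n_params),
              class = "site_model_fit")
  }
  lrt <- likelihood_ratio_test(fake("M0", -100, 15), fake("M3", -95, 19))
  expect_equal(lrt$two_delta_l, 10)
  expect_identical(lrt$df, 4L)
  expect_equal(lrt$p_value, pchisq(10, 4, lower.tail = FALSE))

  lrt2 <- likelihood_ratio_test(fake("M7", -50, 16), fake("M8", -49, 18))
  expect_identical(lrt2$df, 2L)

  expect_error(likelihood_ratio_test(fake("M0", -100, 15), fake("M8", -95, 18)),
               "not a supported nested pair")
  expect_error(likelihood_ratio_test(fake("M7", -50, 16), fake("M8", -51, 18)),
               "lower likelihood")
})

test_that("positively_selected_sites thresholds and stars", {
  fake_fit <- structure(list(
    model_name = "M8",
    classes = data.frame(prop = c(0.9, 0.1), omega = c(0.2, 3)),
    pss = c(0.96, 0.65, 0.85, 0.2, 0.97)
  ), class = "site_model_fit")
  out <- positively_selected_sites(fake_fit)
  expect_identical(out$site, c(1L, 3L, 5L))
  expect_identical(out$starred, c(TRUE, FALSE, TRUE))

  # monotone in report_floor: lowering the floor never removes a site
  lo <- positively_selected_sites(fake_fit, report_floor = 0.5)
  expect_true(all(out$site %in% lo$site))

  no_sel <- structure(list(
    model_name = "M7",
    classes = data.frame(prop = 1, omega = 0.4),
    pss = rep(0, 5)
  ), class = "site_model_fit")
  expect_identical(nrow(positively_selected_sites(no_sel)), 0L)
})

test_that("free-ratio branch model finds the selected lineage", {
  # one long branch evolved at omega = 3, the rest at 0.2
  tr <- tree6(0.25, 0.15)
  m_bg <- codon_model(2, data.frame(prop = 1, omega = 0.2))
  sim <- simulate_codon_alignment(tr, m_bg, 300, seed = 41)
  # re-evolve tip t1 from its parent under omega = 3
  eig <- seldiv:::gy94_eigen(2, 3, m_bg$codon_freqs)
  P <- seldiv:::gy94_pmat(eig, 0.8)
  prep_states <- match(sim$alignment$codons["t2", ], sense_codons())
  set.seed(99)
  new_t1 <- vapply(prep_states, function(s) {
    sample.int(61, 1, prob = P[s, ])
  }, integer(1))
  rows <- codon_rows(sim$alignment)
  rows["t1"] <- paste(sense_codons()[new_t1], collapse = "")
  aln <- codon_alignment(rows, check_stops = FALSE)

  one <- fit_branch_model(aln, tr, "one_ratio", settings = list(n_starts = 1))
  free <- fit_branch_model(aln, tr, "free_ratio",
                           settings = list(n_starts = 1, null_fit = one))
  expect_gte(free$lnL, one$lnL - 1e-4)
  expect_identical(free$lrt$df, 8L)   # 9 edges - 1
  expect_gt(free$omega_by_branch[["t1"]], 1)
  expect_true("t1" %in% free$flagged_branches)
  # background branches stay below 1
  bg <- setdiff(names(free$omega_by_branch),
                c("t1", free$unidentifiable_branches))
  expect_true(mean(free$omega_by_branch[bg] < 1) >= 0.8)
})

test_that("BEB-lite posteriors are valid and shrink extreme NEB calls", {
  cls <- rbind(data.frame(prop = 0.9 * rep(0.1, 10),
                          omega = beta_omega_classes(0.5, 1.5)$omega),
               data.frame(prop = 0.1, omega = 3))
  m <- codon_model(2, cls)
  sim <- simulate_codon_alignment(tree6(0.3, 0.2), m, 120, seed = 61)
  f7 <- fit_site_model(sim$alignment, tree6(0.3, 0.2), "M7",
                       settings = list(n_starts = 1))
  f8 <- fit_site_model(sim$alignment, tree6(0.3, 0.2), "M8",
                       settings = list(n_starts = 1, init_fit = f7))
  beb <- beb_lite_posteriors(f8, sim$alignment, grid_size = 5)
  expect_length(beb, 120)
  expect_true(all(beb >= 0 & beb <= 1))
  expect_false(anyNA(beb))
  # the strongest NEB site stays at or above the BEB-lite median
  expect_gte(beb[which.max(f8$pss)], stats::median(beb))
  expect_error(beb_lite_posteriors(f7, sim$alignment), "M8")
})

test_that("codon_frequencies modes are proper distributions", {
  m <- codon_model(2, data.frame(prop = 1, omega = 0.5))
  sim <- simulate_codon_alignment(tree6(), m, 100, seed = 55)
  for (mode in c("F3x4", "F1x4", "equal")) {
    pi <- codon_frequencies(sim$alignment, mode)
    expect_length(pi, 61)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_true(all(pi > 0))
  }
})

test_that("beta discretization uses bin medians", {
  cls <- beta_omega_classes(2, 3, 10)
  expect_equal(cls$prop, rep(0.1, 10))
  expect_equal(cls$omega, qbeta(seq(0.05, 0.95, by = 0.1), 2, 3))
  expect_true(all(diff(cls$omega) > 0))
})
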