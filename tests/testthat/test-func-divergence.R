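test_that("fitch_site_changes counts minimum changes with missing data", {
  aln <- protein_alignment(c(a1 = "AAC", a2 = "AAG", b1 = "ACA", b2 = "AC-"))
  tr <- tree_cherries()
  ch <- fitch_site_changes(aln, tr)
  # col 1 constant -> 0; col 2 (A,A,C,C) -> 1; col 3 (C,G,A,-) -> 2
  expect_identical(ch, c(0L, 1L, 2L))

  # gaps never force a change
  aln2 <- protein_alignment(c(a1 = "A", a2 = "-", b1 = "A", b2 = "-"))
  expect_identical(fitch_site_changes(aln2, tr), 0L)
  # all-missing column gives 0
  aln3 <- protein_alignment(c(a1 = "-", a2 = "-", b1 = "-", b2 = "-"))
  expect_identical(fitch_site_changes(aln3, tr), 0L)

  expect_error(fitch_site_changes(aln, ape::read.tree(text = "((a1,zz),b1);")),
               "lacks ids")
})

test_that("fitch counts agree with phangorn on random alignments", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  tr <- ape::rtree(8)
  tr$tip.label <- paste0("s", 1:8)
  mat <- matrix(sample(c("A", "C", "D", "E", "F"), 8 * 40, replace = TRUE), 8)
  aln <- protein_alignment(setNames(apply(mat, 1, paste0, collapse = ""),
                                    tr$tip.label))
  ours <- fitch_site_changes(aln, tr)
  pd <- phangorn::phyDat(mat, type = "AA")
  names(pd) <- tr$tip.label
  theirs <- phangorn::fitch(tr, pd, site = "site")
  expect_identical(ours, as.integer(theirs))
})

test_that("ancestral_states applies consensus then alphabetical tie-breaks", {
  tr <- tree_cherries()
  # constant column
  expect_identical(
    ancestral_states(protein_alignment(
      c(a1 = "A", a2 = "A", b1 = "A", b2 = "A")), tr),
    c("A"))
  # cherry subtree with a 1-1 tie: alphabetical winner
  cherry <- ape::read.tree(text = "(a1:1,a2:1);")
  expect_identical(
    ancestral_states(protein_alignment(c(a1 = "C", a2 = "A")), cherry), "A")
  # consensus breaks the tie before the alphabet
  sub3 <- ape::read.tree(text = "((a1:1,a2:1):1,a3:1);")
  aln3 <- protein_alignment(c(a1 = "C", a2 = "G", a3 = "C"))
  expect_identical(ancestral_states(aln3, sub3), "C")
  # all-gap column -> missing marker
  expect_identical(
    ancestral_states(protein_alignment(
      c(a1 = "-", a2 = "-", b1 = "-", b2 = "-")), tr),
    NA_character_)
})

test_that("type-I estimator recovers theta and calibrates at the null", {
  sim <- simulate_rate_shift_counts(500, theta = 0.5, alpha = 0.5,
                                    d1 = 2, d2 = 2, seed = 19)
  fit <- fit_type1(sim$counts)
  expect_gt(fit$theta1, 0.35)
  expect_lt(fit$theta1, 0.65)
  expect_true(all(fit$qk >= 0 & fit$qk <= 1))
  # mixture-posterior consistency
  expect_equal(mean(fit$qk), fit$theta1, tolerance = 0.05)
  expect_true(is.finite(fit$se) && fit$se > 0)
  expect_gt(fit$lrt, qchisq(0.95, 1))

  # label-swap invariance
  fit_sw <- fit_type1(sim$counts[, 2:1])
  expect_equal(fit_sw$theta1, fit$theta1, tolerance = 1e-5)
  expect_equal(fit_sw$d1, fit$d2)

  # small null sample: LRT rarely exceeds the chi-squared threshold
  null_lrt <- vapply(1:5, function(r) {
    fit_type1(simulate_rate_shift_counts(400, 0, 0.5, 2, 2,
                                         seed = 600 + r)$counts)$lrt
  }, numeric(1))
  expect_gte(mean(null_lrt < qchisq(0.95, 1)), 0.8)

  expect_error(fit_type1(cbind(rep(0L, 50), rpois(50, 1))), "zero inferred")
  expect_warning(fit_type1(cbind(rpois(10, 2) + 1, rpois(10, 2) + 1)),
                 "fewer than 20")
})

test_that("type1_caas thresholds and is monotone", {
  res <- structure(list(qk = c(0.95, 0.5, 0.91)), class = "type1_result")
  out <- type1_caas(res, 0.9)
  expect_identical(out$site, c(1L, 3L))
  expect_identical(nrow(type1_caas(res, 1.0)), 0L)
  # lowering the threshold never removes a site
  lo <- type1_caas(res, 0.4)
  expect_true(all(out$site %in% lo$site))
})

test_that("property partitions cover the 20 amino acids", {
  for (nm in c("charge", "polarity", "hydrophobicity")) {
    part <- property_partition(nm)
    expect_setequal(unlist(part), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    expect_identical(anyDuplicated(unlist(part)), 0L)
  }
})

# The hand-built Type-II scenarios live in helper-fixtures.R
# (type2_fixture) because the acceptance suite reuses them.

test_that("type-II closed form hits its fixed points", {
  tr <- tree_cherries()
  clusters <- c(a1 = "ca", a2 = "ca", b1 = "cb", b2 = "cb")
  fit <- fit_type2(type2_fixture(), tr, clusters)
  expect_equal(fit$p_r0, 0.2)
  expect_equal(fit$pi_r, 1)
  expect_equal(fit$theta2, 1)   # all differing pairs radical -> exactly 1
  expect_identical(sum(fit$site_class == "radical_difference"), 5L)
  expect_true(all(fit$qk[fit$site_class == "radical_difference"] > 0))

  # pi_R = p_r0 gives exactly 0:
  #   diffs: K/D radical, A/V, L/I, S/T conserved  -> pi_R = 1/4
  #   events: K/D radical, A/V, L/I, S/T conserved -> p_r0 = 1/4
  aln0 <- protein_alignment(c(a1 = "KALSKAGG", a2 = "KALSDVGG",
                              b1 = "DVITAALS", b2 = "DVITAAIT"))
  fit0 <- fit_type2(aln0, tr, clusters)
  expect_equal(fit0$p_r0, 0.25)
  expect_equal(fit0$pi_r, 0.25)
  expect_equal(fit0$theta2, 0)

  # pi_R < p_r0 gives a negative estimate: drop the radical difference
  aln_neg <- protein_alignment(c(a1 = "ALSFKAGG", a2 = "ALSFDVGG",
                                 b1 = "VITYAALS", b2 = "VITYAAIT"))
  fit_neg <- fit_type2(aln_neg, tr, clusters)
  expect_equal(fit_neg$pi_r, 0)
  expect_lt(fit_neg$theta2, 0)
  expect_true(all(fit_neg$qk == 0))
})

test_that("type-II is invariant to property-group relabeling and flags
           the no-difference case", {
  tr <- tree_cherries()
  clusters <- c(a1 = "ca", a2 = "ca", b1 = "cb", b2 = "cb")
  aln <- type2_fixture()
  part <- property_partition("charge")
  names(part) <- c("g1", "g2", "g3")
  expect_equal(fit_type2(aln, tr, clusters, part)$theta2,
               fit_type2(aln, tr, clusters)$theta2)

  same <- protein_alignment(c(a1 = "AAAA", a2 = "AAAA",
                              b1 = "AAAA", b2 = "AAAA"))
  res <- fit_type2(same, tr, clusters)
  expect_true(is.na(res$theta2))
  expect_identical(res$n_diff, 0L)
})

test_that("change_count_table builds per-cluster counts", {
  aln <- protein_alignment(c(a1 = "AAC", a2 = "AAG", b1 = "ACA", b2 = "ACC"))
  counts <- change_count_table(aln, tree_cherries(),
                               c(a1 = "x", a2 = "x", b1 = "y", b2 = "y"))
  expect_identical(colnames(counts), c("x", "y"))
  expect_identical(counts[, "x"], c(0L, 0L, 1L))
  expect_identical(counts[, "y"], c(0L, 0L, 1L))
  expect_error(change_count_table(aln, tree_cherries(),
                                  c(a1 = "x", a2 = "x", b1 = "y", b2 = "z")),
               "exactly 2 clusters")
})
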