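test_that("p_distance handles modes and deletion schemes", {
  expect_equal(p_distance(c(x = "AAAA", y = "AAAT"),
                          mode = "nucleotide")["x", "y"], 0.25)
  # pairwise deletion: 3 comparable positions, 1 difference
  expect_equal(p_distance(c(x = "A-AA", y = "AAAT"),
                          mode = "nucleotide")["x", "y"], 1 / 3)
  # A->G is a transition: transversion-only numerator gives 0
  expect_equal(p_distance(c(x = "AAAA", y = "AAAG"),
                          mode = "nucleotide_transversion")["x", "y"], 0)
  expect_equal(p_distance(c(x = "AAAA", y = "AAAC"),
                          mode = "nucleotide_transversion")["x", "y"], 0.25)
  # complete deletion drops the gapped column for every pair
  D <- p_distance(c(x = "A-AA", y = "AAAT", z = "ACAA"),
                  mode = "nucleotide", deletion = "complete")
  expect_equal(D["y", "z"], 1 / 3)
  # no comparable positions -> NA
  D2 <- p_distance(c(x = "A--", y = "-TT", z = "ATT"), mode = "nucleotide")
  expect_true(is.na(D2["x", "y"]))

  # symmetry, zero diagonal, [0, 1] range on simulated data
  m <- codon_model(2, data.frame(prop = 1, omega = 0.5))
  sim <- simulate_codon_alignment(tree6(), m, 60, seed = 8)
  D3 <- p_distance(sim$alignment, mode = "nucleotide")
  expect_equal(D3, t(D3))
  expect_true(all(diag(D3) == 0))
  expect_true(all(D3 >= 0 & D3 <= 1))
})

test_that("p_distance agrees with ape::dist.dna raw distances", {
  skip_if_not_installed("ape")
  m <- codon_model(2, data.frame(prop = 1, omega = 0.5))
  sim <- simulate_codon_alignment(tree6(), m, 50, seed = 14)
  rows <- codon_rows(sim$alignment)
  D <- p_distance(rows, mode = "nucleotide")
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(rows), ""), identity)))
  Dape <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(D[rownames(Dape), colnames(Dape)], Dape, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("neighbor_joining recovers an additive tree exactly", {
  D <- matrix(c(0, 5, 9, 10,
                5, 0, 10, 11,
                9, 10, 0, 9,
                10, 11, 9, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- neighbor_joining(D)
  # path lengths reproduce the input distances
  expect_equal(ape::cophenetic.phylo(tree)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  # branch lengths are (2, 3, 3, 4, 5)
  expect_equal(sort(tree$edge.length), c(2, 3, 3, 4, 5), tolerance = 1e-9)
  # AB|CD split is present
  ab <- ape::getMRCA(ape::root(tree, "D"), c("A", "B"))
  expect_length(ape::extract.clade(ape::root(tree, "D"), ab)$tip.label, 2)

  # three taxa: closed-form star solution
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  expect_equal(ape::cophenetic.phylo(t3)[rownames(D3), colnames(D3)], D3,
               tolerance = 1e-9)

  D[1, 2] <- D[2, 1] <- NA
  expect_error(neighbor_joining(D), "undefined distance between A and B")
})

test_that("bootstrap supports are deterministic and order-invariant", {
  m <- codon_model(2, data.frame(prop = 1, omega = 0.3))
  sim <- simulate_codon_alignment(tree6(0.3, 0.2), m, 120, seed = 17)
  prot <- translate_alignment(sim$alignment)

  b1 <- bootstrap_support(prot, n_reps = 50, seed = 99)
  b2 <- bootstrap_support(prot, n_reps = 50, seed = 99)
  expect_identical(b1$node.label, b2$node.label)

  # reordering the input sequences must not change the supports
  perm <- protein_alignment(setNames(
    apply(prot$mat, 1, paste0, collapse = ""), prot$ids)[c(4, 2, 6, 1, 3, 5)])
  b3 <- bootstrap_support(perm, n_reps = 50, seed = 99)
  s1 <- setNames(b1$node.label, vapply(seq_len(b1$Nnode), function(n) {
    paste(sort(ape::extract.clade(b1, n + 6)$tip.label), collapse = ",")
  }, character(1)))
  s3 <- setNames(b3$node.label, vapply(seq_len(b3$Nnode), function(n) {
    paste(sort(ape::extract.clade(b3, n + 6)$tip.label), collapse = ",")
  }, character(1)))
  expect_identical(s1[sort(names(s1))], s3[sort(names(s3))])

  # a single replicate can only give 0 or 100
  b4 <- bootstrap_support(prot, n_reps = 1, seed = 5)
  expect_true(all(as.integer(b4$node.label[-1]) %in% c(0L, 100L)))

  expect_error(
    bootstrap_support(protein_alignment(c(a = "M", b = "M", c = "K")),
                      n_reps = 2, seed = 1),
    "fewer than 2 columns")
})

test_that("strong clean signal gives full supports", {
  # two deeply separated cherries, no homoplasy
  rows <- c(a1 = strrep("AAAAA", 8), a2 = strrep("AAAAC", 8),
            b1 = strrep("TTTTT", 8), b2 = strrep("TTTTG", 8))
  aln <- protein_alignment(rows)
  b <- bootstrap_support(aln, n_reps = 25, seed = 3)
  expect_true(all(as.integer(b$node.label[-1]) == 100L))
})

test_that("strict_clock_age scales linearly from the calibration", {
  expect_equal(strict_clock_age(0.2, d_cal = 0.4, t_cal = 200), 100)
  expect_equal(strict_clock_age(0.4, d_cal = 0.4, t_cal = 200), 200)
  expect_equal(strict_clock_age(0, d_cal = 0.4, t_cal = 200), 0)
  expect_error(strict_clock_age(0.2, d_cal = 0, t_cal = 200), "> 0")
  expect_error(strict_clock_age(-1, d_cal = 0.4, t_cal = 200), ">= 0")
})

test_that("newick I/O round-trips topology, lengths and supports", {
  p <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2)90:3,C:4);", p)
  tree <- read_newick(p)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  expect_identical(tree$node.label[2], "90")

  p2 <- tempfile(fileext = ".nwk")
  write_newick(tree, p2)
  tree2 <- read_newick(p2)
  expect_identical(ape::write.tree(tree), ape::write.tree(tree2))
  expect_equal(tree2$edge.length, tree$edge.length, tolerance = 1e-6)

  writeLines("((A,B),(A,C));", p)
  expect_error(read_newick(p), "duplicate leaf")
  writeLines("((A,B),(C,D);", p)
  expect_error(read_newick(p), "unbalanced")
})
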