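# Seeded simulators for every analysis stage: codon alignments under
# site-class omega mixtures, per-cluster change counts with rate shifts,
# grouped protein alignments with planted SDP columns, and fourfold-
# degenerate paralog pairs for 4DTv.  Each generator is a pure function of
# (parameters, seed) and restores the caller's RNG state.

new_truth <- function(..., seed) {
  structure(list(..., seed = seed), class = "simulation_truth")
}

#' Simulate a codon alignment under a site-class omega mixture
#'
#' Each site draws an omega class from the model's mixture; the root codon
#' is drawn from the stationary frequencies and evolved down the tree with
#' the class-specific transition matrices.
#'
#' @param tree A `phylo` with branch lengths (expected substitutions per
#'   codon).
#' @param model A [codon_model()].
#' @param n_codons Number of codon sites.
#' @param seed Integer seed.
#' @return List with `alignment` (a `codon_alignment` over the tree's tips)
#'   and `truth` (per-site class index and omega, plus parameters).
#' @export
simulate_codon_alignment <- function(tree, model, n_codons, seed) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "codon_model"),
            n_codons >= 1)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  pi <- model$codon_freqs
  classes <- model$omega_classes
  K <- nrow(classes)
  site_class <- sample.int(K, n_codons, replace = TRUE, prob = classes$prop)
  eigs <- lapply(classes$omega, function(om) gy94_eigen(model$kappa, om, pi))

  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, n_codons)
  root <- tree$edge[nrow(tree$edge), 1]
  states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)

  for (e in rev(seq_len(nrow(tree$edge)))) {    # preorder from the root
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    for (k in unique(site_class)) {
      P <- gy94_pmat(eigs[[k]], tree$edge.length[e])
      idx <- which(site_class == k)
      for (s in unique(states[parent, idx])) {
        at <- idx[states[parent, idx] == s]
        states[child, at] <- sample.int(61, length(at), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }

  cod <- sense_codons()
  rows <- apply(states[seq_len(n_tip), , drop = FALSE], 1,
                function(x) paste(cod[x], collapse = ""))
  aln <- codon_alignment(setNames(rows, tree$tip.label), check_stops = FALSE)
  list(alignment = aln,
       truth = new_truth(site_class = site_class,
                         site_omega = classes$omega[site_class],
                         model = model, seed = seed))
}

#' Simulate per-site change counts with rate shifts
#'
#' With probability `theta` a site draws independent gamma(alpha, alpha)
#' rates for the two clusters (a rate shift); otherwise one shared rate.
#' Counts are Poisson with means `rate * d1` and `rate * d2`.
#'
#' @param n_sites Number of sites.
#' @param theta Probability of a rate shift, in \[0, 1\].
#' @param alpha Gamma shape (> 0).
#' @param d1,d2 Expected change counts per cluster (> 0).
#' @param seed Integer seed.
#' @return List with `counts` (sites x 2 matrix) and `truth` (logical
#'   `shifted` per site).
#' @export
simulate_rate_shift_counts <- function(n_sites, theta, alpha, d1, d2, seed) {
  stopifnot(theta >= 0, theta <= 1, alpha > 0, d1 > 0, d2 > 0, n_sites >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shifted <- runif(n_sites) < theta
  r1 <- rgamma(n_sites, shape = alpha, rate = alpha)
  r2 <- ifelse(shifted, rgamma(n_sites, shape = alpha, rate = alpha), r1)
  counts <- cbind(cluster1 = rpois(n_sites, r1 * d1),
                  cluster2 = rpois(n_sites, r2 * d2))
  list(counts = counts,
       truth = new_truth(shifted = shifted, theta = theta, alpha = alpha,
                         d1 = d1, d2 = d2, seed = seed))
}

#' Simulate a grouped protein alignment with planted SDP columns
#'
#' Planted columns draw each group's residues from that group's assigned
#' residue (with a small error rate); background columns are i.i.d. from a
#' profile shared across groups, so residue and group label are independent
#' there.
#'
#' @param n_per_group Number of sequences per group; named vector (names are
#'   group labels) or unnamed (labels `group1`, `group2`, ...).
#' @param n_cols Total number of columns.
#' @param sdp_spec Data frame with a `column` field plus one residue column
#'   per group label.
#' @param background_profile Residue probabilities for background columns
#'   (named over the 20 amino acids); uniform by default.
#' @param error_rate Per-sequence probability that a planted column draws
#'   from the background profile instead (default 0.05).
#' @param seed Integer seed.
#' @return List with `alignment`, `groups` and `truth` (logical `is_sdp`
#'   per column).
#' @export
simulate_grouped_alignment <- function(n_per_group, n_cols, sdp_spec,
                                       background_profile = NULL,
                                       error_rate = 0.05, seed = 1L) {
  if (is.null(names(n_per_group))) {
    names(n_per_group) <- paste0("group", seq_along(n_per_group))
  }
  labs <- names(n_per_group)
  sdp_spec <- as.data.frame(sdp_spec)
  if (nrow(sdp_spec)) {
    if (!all(c("column", labs) %in% names(sdp_spec))) {
      stop("sdp_spec needs 'column' plus one residue column per group label")
    }
    if (anyDuplicated(sdp_spec$column)) stop("duplicate planted column in sdp_spec")
    if (any(sdp_spec$column < 1 | sdp_spec$column > n_cols)) {
      stop("planted column outside 1..n_cols")
    }
    bad <- !unlist(sdp_spec[labs]) %in% AA20
    if (any(bad)) stop("sdp_spec residues must be standard amino acids")
  }
  if (is.null(background_profile)) {
    background_profile <- setNames(rep(1 / 20, 20), AA20)
  }
  stopifnot(setequal(names(background_profile), AA20))
  p_bg <- as.numeric(background_profile[AA20])
  p_bg <- p_bg / sum(p_bg)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  groups <- rep(labs, n_per_group)
  ids <- paste0(groups, "_", unlist(lapply(n_per_group, seq_len)))
  n_seq <- length(ids)
  mat <- matrix(sample(AA20, n_seq * n_cols, replace = TRUE, prob = p_bg),
                nrow = n_seq)
  for (r in seq_len(nrow(sdp_spec))) {
    j <- sdp_spec$column[r]
    for (lab in labs) {
      rows <- which(groups == lab)
      res <- rep(sdp_spec[[lab]][r], length(rows))
      err <- runif(length(rows)) < error_rate
      res[err] <- sample(AA20, sum(err), replace = TRUE, prob = p_bg)
      mat[rows, j] <- res
    }
  }
  aln <- protein_alignment(setNames(apply(mat, 1, paste0, collapse = ""), ids))
  is_sdp <- seq_len(n_cols) %in% sdp_spec$column
  list(alignment = aln, groups = setNames(groups, ids),
       truth = new_truth(is_sdp = is_sdp, error_rate = error_rate, seed = seed))
}

k2p_step_probs <- function(d, kappa) {
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    transition = 0.25 + 0.25 * e1 - 0.5 * e2,
    transversion_each = 0.25 - 0.25 * e1)
}

k2p_evolve <- function(nuc, d, kappa) {
  p <- k2p_step_probs(d, kappa)
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
  u <- runif(length(nuc))
  out <- nuc
  ts <- u >= p["same"] & u < p["same"] + p["transition"]
  out[ts] <- ts_partner[nuc[ts]]
  tv <- u >= p["same"] + p["transition"]
  if (any(tv)) {
    pick <- runif(sum(tv)) < 0.5
    out[tv] <- mapply(function(n, first) tv_partners[[n]][if (first) 1 else 2],
                      nuc[tv], pick)
  }
  out
}

#' Simulate a fourfold-degenerate paralog pair
#'
#' Generates `n_codons` codons from the fourfold-degenerate boxes; the two
#' copies are identical except at third positions, which evolve away from a
#' common ancestor under a K2P process, each copy along a branch of half the
#' given divergence.  In saturation mode both third positions are drawn
#' i.i.d. uniform over the four nucleotides, which is the infinite-time
#' limit.
#'
#' @param n_codons Number of fourfold-degenerate codon sites.
#' @param third_pos_branch_length Total third-position divergence between
#'   the copies (expected substitutions per site); ignored in saturation
#'   mode.
#' @param kappa Transition/transversion rate ratio of the K2P process.
#' @param seed Integer seed.
#' @param saturation Draw both third positions i.i.d. uniform instead.
#' @return A two-row `codon_alignment` (`paralog_a`, `paralog_b`).
#' @export
simulate_paralog_pair <- function(n_codons, third_pos_branch_length = 0.5,
                                  kappa = 2, seed = 1L, saturation = FALSE) {
  stopifnot(n_codons >= 1, third_pos_branch_length >= 0, kappa > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nucs <- c("A", "C", "G", "T")
  prefix <- sample(fourfold_prefixes(), n_codons, replace = TRUE)
  if (saturation) {
    third_a <- sample(nucs, n_codons, replace = TRUE)
    third_b <- sample(nucs, n_codons, replace = TRUE)
  } else {
    anc <- sample(nucs, n_codons, replace = TRUE)
    third_a <- k2p_evolve(anc, third_pos_branch_length / 2, kappa)
    third_b <- k2p_evolve(anc, third_pos_branch_length / 2, kappa)
  }
  codon_alignment(c(paralog_a = paste0(prefix, third_a, collapse = ""),
                    paralog_b = paste0(prefix, third_b, collapse = "")),
                  check_stops = FALSE)
}

#' Balanced test tree
#'
#' A deterministic balanced topology with uniform branch lengths, convenient
#' for simulations.
#'
#' @param n_tips Number of tips (power of 2 recommended).
#' @param branch_length Length of every edge.
#' @return A `phylo` tree with tips `t1..tn`.
#' @export
balanced_tree <- function(n_tips, branch_length = 0.2) {
  tree <- ape::stree(n_tips, type = "balanced")
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree$edge.length <- rep(branch_length, nrow(tree$edge))
  ape::unroot(tree)
}
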