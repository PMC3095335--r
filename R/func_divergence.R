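# Type-I (rate-shift) and Type-II (property-shift) functional divergence
# between two clusters of a protein alignment.  Per-site change counts come
# from Fitch parsimony within each cluster's subtree; Type-I fits a
# gamma-Poisson mixture in which a site's rate is either shared between the
# clusters or drawn independently (probability theta_I).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_FULL_MASK <- bitwShiftL(1L, 20L) - 1L

aa_masks <- function(column) {
  idx <- match(column, AA20)
  m <- ifelse(is.na(idx), AA_FULL_MASK, bitwShiftL(1L, idx - 1L))
  as.integer(m)
}

mask_to_states <- function(mask) AA20[bitwAnd(mask, bitwShiftL(1L, 0:19)) != 0L]

# Fitch bottom-up pass for one column; returns list(count, root_mask).
fitch_column <- function(masks, edge, n_tip) {
  sets <- integer(max(edge))
  sets[seq_len(n_tip)] <- masks
  seen <- logical(max(edge))
  count <- 0L
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    cs <- sets[child]
    if (!seen[parent]) {
      sets[parent] <- cs
      seen[parent] <- TRUE
    } else {
      inter <- bitwAnd(sets[parent], cs)
      if (inter != 0L) {
        sets[parent] <- inter
      } else {
        sets[parent] <- bitwOr(sets[parent], cs)
        count <- count + 1L
      }
    }
  }
  list(count = count, root_mask = sets[edge[nrow(edge), 1]])
}

cluster_subtree <- function(aln, tree, ids) {
  missing <- setdiff(ids, tree$tip.label)
  if (length(missing)) stop("tree lacks tips: ", paste(missing, collapse = ", "))
  missing <- setdiff(ids, aln$ids)
  if (length(missing)) stop("alignment lacks ids: ", paste(missing, collapse = ", "))
  if (length(ids) < 2L) stop("a cluster needs at least 2 sequences")
  stats::reorder(ape::keep.tip(tree, ids), "postorder")
}

#' Per-site Fitch parsimony change counts on a subtree
#'
#' Gaps and ambiguous residues are treated as missing data (they never force
#' a change); a column with no data gets 0.
#'
#' @param aln A `protein_alignment`.
#' @param subtree A `phylo` whose tips are a subset of the alignment ids
#'   (at least 2).
#' @return Integer vector of minimum change counts, one per column.
#' @export
fitch_site_changes <- function(aln, subtree) {
  stopifnot(inherits(aln, "protein_alignment"), inherits(subtree, "phylo"))
  subtree <- stats::reorder(subtree, "postorder")
  missing <- setdiff(subtree$tip.label, aln$ids)
  if (length(missing)) stop("alignment lacks ids: ", paste(missing, collapse = ", "))
  mat <- aln$mat[subtree$tip.label, , drop = FALSE]
  n_tip <- length(subtree$tip.label)
  vapply(seq_len(ncol(mat)), function(j) {
    fitch_column(aa_masks(mat[, j]), subtree$edge, n_tip)$count
  }, integer(1))
}

# consensus-then-alphabetical choice among candidate states for a column
pick_state <- function(candidates, column) {
  if (!length(candidates)) return(NA_character_)
  tab <- table(factor(column[column %in% AA20], levels = AA20))
  freq <- tab[candidates]
  winners <- candidates[freq == max(freq)]
  sort(winners)[1]
}

#' Fitch ancestral state at the root of a cluster subtree
#'
#' Bottom-up Fitch state sets; ties are broken by the cluster's column
#' consensus, then alphabetically.  Columns with no data give `NA`.
#'
#' @inheritParams fitch_site_changes
#' @return Character vector of root states (one per column).
#' @export
ancestral_states <- function(aln, subtree) {
  stopifnot(inherits(aln, "protein_alignment"), inherits(subtree, "phylo"))
  subtree <- stats::reorder(subtree, "postorder")
  missing <- setdiff(subtree$tip.label, aln$ids)
  if (length(missing)) stop("alignment lacks ids: ", paste(missing, collapse = ", "))
  mat <- aln$mat[subtree$tip.label, , drop = FALSE]
  n_tip <- length(subtree$tip.label)
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (!any(col %in% AA20)) return(NA_character_)
    root <- fitch_column(aa_masks(col), subtree$edge, n_tip)$root_mask
    pick_state(mask_to_states(root), col)
  }, character(1))
}

# Enumerate substitution events on a subtree by a full Fitch pass with the
# consensus/alphabetical tie rule; returns data.frame(site, from, to).
fitch_events <- function(aln, subtree, sites = NULL) {
  subtree <- stats::reorder(subtree, "postorder")
  mat <- aln$mat[subtree$tip.label, , drop = FALSE]
  n_tip <- length(subtree$tip.label)
  edge <- subtree$edge
  if (is.null(sites)) sites <- seq_len(ncol(mat))
  out <- list()
  for (j in sites) {
    col <- mat[, j]
    if (sum(col %in% AA20) < 2L) next
    masks <- aa_masks(col)
    sets <- integer(max(edge))
    sets[seq_len(n_tip)] <- masks
    seen <- logical(max(edge))
    for (e in seq_len(nrow(edge))) {
      parent <- edge[e, 1]; child <- edge[e, 2]
      if (!seen[parent]) {
        sets[parent] <- sets[child]; seen[parent] <- TRUE
      } else {
        inter <- bitwAnd(sets[parent], sets[child])
        sets[parent] <- if (inter != 0L) inter else bitwOr(sets[parent], sets[child])
      }
    }
    root <- edge[nrow(edge), 1]
    state <- character(max(edge))
    state[root] <- pick_state(mask_to_states(sets[root]), col)
    for (e in rev(seq_len(nrow(edge)))) {   # preorder
      parent <- edge[e, 1]; child <- edge[e, 2]
      if (child <= n_tip && !(col[child] %in% AA20)) next   # missing tip
      cand <- mask_to_states(sets[child])
      state[child] <- if (state[parent] %in% cand) state[parent]
                      else pick_state(cand, col)
      if (state[child] != state[parent]) {
        out[[length(out) + 1L]] <- data.frame(
          site = j, from = state[parent], to = state[child],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(site = integer(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Per-site change counts for two clusters
#'
#' @param aln A `protein_alignment`.
#' @param tree A `phylo` containing all cluster members as tips.
#' @param clusters Named character vector mapping sequence id to cluster
#'   label; exactly 2 distinct labels, each with >= 2 members.
#' @return Integer matrix (sites x 2 clusters) of Fitch change counts, with
#'   cluster labels as column names.
#' @export
change_count_table <- function(aln, tree, clusters) {
  labs <- sort(unique(clusters))
  if (length(labs) != 2L) stop("exactly 2 clusters are supported, got ", length(labs))
  counts <- sapply(labs, function(lab) {
    ids <- names(clusters)[clusters == lab]
    fitch_site_changes(aln, cluster_subtree(aln, tree, ids))
  })
  colnames(counts) <- labs
  counts
}

# log pmf of the gamma(alpha, alpha)-Poisson marginal: NB(size = alpha, mu = d)
lnb <- function(x, alpha, d) dnbinom(x, size = alpha, mu = d, log = TRUE)

# log pmf of the shared-rate bivariate gamma-Poisson
lbnb <- function(x1, x2, alpha, d1, d2) {
  lgamma(alpha + x1 + x2) - lgamma(alpha) - lfactorial(x1) - lfactorial(x2) +
    x1 * log(d1) + x2 * log(d2) + alpha * log(alpha) -
    (alpha + x1 + x2) * log(alpha + d1 + d2)
}

type1_site_loglik <- function(theta, alpha, x1, x2, d1, d2) {
  ind <- lnb(x1, alpha, d1) + lnb(x2, alpha, d2)
  shared <- lbnb(x1, x2, alpha, d1, d2)
  if (theta <= 0) return(list(ll = shared, ind = ind, shared = shared))
  if (theta >= 1) return(list(ll = ind, ind = ind, shared = shared))
  mx <- pmax(ind, shared)
  ll <- mx + log(theta * exp(ind - mx) + (1 - theta) * exp(shared - mx))
  list(ll = ll, ind = ind, shared = shared)
}

num_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  hs <- h * pmax(abs(x), 1)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ei <- ej <- numeric(n)
      ei[i] <- hs[i]; ej[j] <- hs[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hs[i] * hs[j])
    }
  }
  H
}

#' Type-I functional divergence (rate-shift) estimator
#'
#' Fits, by maximum likelihood, a two-state mixture to the per-site change
#' counts of two clusters: with probability `theta_I` a site's evolutionary
#' rate is drawn independently in each cluster (rate shift), otherwise a
#' single shared gamma-distributed rate generates both counts.  A shared
#' gamma shape `alpha` is used; cluster means `d1`, `d2` are fixed at the
#' observed average change counts.
#'
#' @param counts Matrix from [change_count_table()] (sites x 2).
#' @return A `type1_result`: `theta1`, `se` (observed Fisher information),
#'   `lrt` (2 log-likelihood difference against `theta = 0`), `p_value`
#'   (chi-squared, 1 df), `alpha`, `d1`, `d2`, `qk` (per-site posterior of
#'   the rate-shift state), `lnL`, and `boundary` (`TRUE` when `theta1` hit
#'   0 or 1).
#' @export
fit_type1 <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L) stop("counts must have exactly 2 cluster columns")
  if (nrow(counts) < 20L) {
    warning("fewer than 20 sites; theta_I estimate will be unstable")
  }
  x1 <- counts[, 1]; x2 <- counts[, 2]
  if (all(x1 == 0) || all(x2 == 0)) {
    stop("a cluster has zero inferred changes at every site (no information)")
  }
  d1 <- mean(x1); d2 <- mean(x2)

  negll <- function(par) {   # par = (theta, log alpha)
    v <- -sum(type1_site_loglik(par[1], exp(par[2]), x1, x2, d1, d2)$ll)
    if (!is.finite(v)) 1e12 else v
  }
  opt <- optim(c(0.3, log(1)), negll, method = "L-BFGS-B",
               lower = c(0, log(0.05)), upper = c(1, log(100)),
               control = list(maxit = 500))
  theta <- opt$par[1]; alpha <- exp(opt$par[2])

  opt0 <- optimize(function(la) negll(c(0, la)), c(log(0.05), log(100)))
  lrt <- max(0, 2 * (opt0$objective - opt$value))

  boundary <- theta <= 1e-6 || theta >= 1 - 1e-6
  se <- NA_real_
  if (!boundary) {
    H <- num_hessian(function(p) negll(c(p[1], log(p[2]))), c(theta, alpha))
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov) && cov[1, 1] > 0) se <- sqrt(cov[1, 1])
  }

  parts <- type1_site_loglik(theta, alpha, x1, x2, d1, d2)
  qk <- if (theta <= 0) rep(0, length(x1))
        else if (theta >= 1) rep(1, length(x1))
        else theta * exp(parts$ind - parts$ll)
  structure(list(theta1 = theta, se = se, lrt = lrt,
                 p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
                 alpha = alpha, d1 = d1, d2 = d2,
                 qk = pmin(pmax(qk, 0), 1), lnL = -opt$value,
                 boundary = boundary), class = "type1_result")
}

#' @export
print.type1_result <- function(x, ...) {
  cat(sprintf("Type-I functional divergence: theta_I = %.3f +/- %s; LRT = %.2f; p = %.3g\n",
              x$theta1, ifelse(is.na(x$se), "NA", sprintf("%.3f", x$se)),
              x$lrt, x$p_value))
  invisible(x)
}

#' Critical amino acid sites from Type-I posteriors
#'
#' @param result A `type1_result`.
#' @param q_threshold Posterior threshold (default 0.9).
#' @return Data frame with `site` and `qk`, sorted by decreasing posterior.
#' @export
type1_caas <- function(result, q_threshold = 0.9) {
  stopifnot(inherits(result, "type1_result"))
  keep <- which(result$qk > q_threshold)
  out <- data.frame(site = keep, qk = result$qk[keep])
  out[order(-out$qk, out$site), , drop = FALSE]
}

#' Amino-acid property partitions
#'
#' Named partitions of the 20 amino acids into physiochemical groups, used
#' to classify a between-cluster replacement as radical (group changes) or
#' conserved.
#'
#' @param name `"charge"` (default), `"polarity"` or `"hydrophobicity"`.
#' @return Named list of character vectors that partition the 20 residues.
#' @export
property_partition <- function(name = c("charge", "polarity", "hydrophobicity")) {
  name <- match.arg(name)
  part <- switch(name,
    charge = list(positive = c("K", "R", "H"), negative = c("D", "E"),
                  neutral = setdiff(AA20, c("K", "R", "H", "D", "E"))),
    polarity = list(polar = c("N", "Q", "S", "T", "Y", "C"),
                    charged = c("D", "E", "K", "R", "H"),
                    nonpolar = setdiff(AA20, c("N", "Q", "S", "T", "Y", "C",
                                               "D", "E", "K", "R", "H"))),
    hydrophobicity = list(hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
                          hydrophilic = setdiff(AA20, c("A", "V", "L", "I",
                                                        "M", "F", "W", "C"))))
  stopifnot(setequal(unlist(part), AA20), !anyDuplicated(unlist(part)))
  part
}

property_group <- function(res, partition) {
  grp <- rep(names(partition), lengths(partition))
  names(grp) <- unlist(partition)
  unname(grp[res])
}

#' Type-II functional divergence (property-shift) estimator
#'
#' Closed-form estimator over cluster-ancestral differences.  Applicable
#' sites are monomorphic within both clusters; among those whose ancestral
#' states differ, replacements are classified radical (property group
#' changes) or conserved.  The background radical probability `p_r0` is the
#' radical fraction among within-cluster substitution events pooled over the
#' remaining sites (0.5 when no such event exists).  Then
#' `theta_II = (pi_R - p_r0) / (1 - p_r0)`, which may be negative.
#'
#' @param aln A `protein_alignment`.
#' @param tree A `phylo` containing the cluster members.
#' @param clusters Named character vector id -> label (exactly 2 labels).
#' @param partition Property partition from [property_partition()].
#' @return A `type2_result`: `theta2` (`NA` when no applicable differing
#'   sites exist), `se` (binomial delta method), `p_r0`, `pi_r`, `n_diff`,
#'   `site_class` (per site: `no_difference`, `conserved_difference`,
#'   `radical_difference`, `not_applicable`) and `qk`.
#' @export
fit_type2 <- function(aln, tree, clusters,
                      partition = property_partition("charge")) {
  labs <- sort(unique(clusters))
  if (length(labs) != 2L) stop("exactly 2 clusters are supported")
  sub1 <- cluster_subtree(aln, tree, names(clusters)[clusters == labs[1]])
  sub2 <- cluster_subtree(aln, tree, names(clusters)[clusters == labs[2]])
  ch1 <- fitch_site_changes(aln, sub1)
  ch2 <- fitch_site_changes(aln, sub2)
  anc1 <- ancestral_states(aln, sub1)
  anc2 <- ancestral_states(aln, sub2)

  applicable <- ch1 == 0L & ch2 == 0L & !is.na(anc1) & !is.na(anc2)
  differing <- applicable & anc1 != anc2
  radical <- differing &
    property_group(anc1, partition) != property_group(anc2, partition)

  site_class <- ifelse(!applicable, "not_applicable",
                ifelse(!differing, "no_difference",
                ifelse(radical, "radical_difference", "conserved_difference")))

  other <- which(!applicable)
  ev <- rbind(fitch_events(aln, sub1, sites = other),
              fitch_events(aln, sub2, sites = other))
  p_r0 <- if (nrow(ev)) {
    mean(property_group(ev$from, partition) != property_group(ev$to, partition))
  } else 0.5
  if (p_r0 >= 1) p_r0 <- 1 - 1e-9   # keep the estimator defined

  n_diff <- sum(differing)
  if (n_diff == 0L) {
    return(structure(list(theta2 = NA_real_, se = NA_real_, p_r0 = p_r0,
                          pi_r = NA_real_, n_diff = 0L,
                          site_class = site_class,
                          qk = rep(0, length(site_class))),
                     class = "type2_result"))
  }
  pi_r <- sum(radical) / n_diff
  theta2 <- (pi_r - p_r0) / (1 - p_r0)
  se <- sqrt(pi_r * (1 - pi_r) / n_diff) / (1 - p_r0)

  qk <- rep(0, length(site_class))
  if (theta2 > 0) {
    qk[radical] <- theta2 / (theta2 + (1 - theta2) * p_r0)
  }
  structure(list(theta2 = theta2, se = se, p_r0 = p_r0, pi_r = pi_r,
                 n_diff = n_diff, site_class = site_class, qk = qk),
            class = "type2_result")
}

#' @export
print.type2_result <- function(x, ...) {
  if (is.na(x$theta2)) {
    cat("Type-II functional divergence: undefined (no applicable differing sites)\n")
  } else {
    cat(sprintf("Type-II functional divergence: theta_II = %.3f +/- %.3f (p_r0 = %.3f, %d differing sites)\n",
                x$theta2, x$se, x$p_r0, x$n_diff))
  }
  invisible(x)
}
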