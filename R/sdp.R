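# Specificity-determining positions: per-column mutual information between
# residue and group label, shuffle-based Z-scores, and an automatic cutoff
# on the ranked scores from a Bernoulli (binomial-tail) estimator.

column_counts <- function(column, groups, labs) {
  ok <- column %in% AA20
  table(factor(column[ok], levels = AA20),
        factor(groups[ok], levels = labs))
}

mi_from_counts <- function(n_ai, pseudocount, q_a, base = 2) {
  N_i <- colSums(n_ai)
  if (any(N_i == 0)) return(0)
  w <- N_i / sum(N_i)
  f_cond <- sweep(n_ai + pseudocount * q_a, 2, N_i + pseudocount, "/")
  f_joint <- sweep(f_cond, 2, w, "*")
  f_a <- rowSums(f_joint)
  terms <- f_joint * log(sweep(f_joint, 1, f_a, "/") %*% diag(1 / w))
  sum(terms[f_joint > 0]) / log(base)
}

#' Mutual information between residue and group at one column
#'
#' `I = sum_{a,i} f(a,i) log2[f(a,i) / (f(a) f(i))]` with the within-group
#' residue distribution smoothed as `(n(a,i) + lambda q_a) / (N_i + lambda)`
#' (`q_a`: overall residue frequencies) and groups weighted by their size.
#' `lambda = 0` gives the plug-in MI.
#'
#' @param aln A `protein_alignment`.
#' @param groups Named character vector id -> group label.
#' @param column Column index.
#' @param pseudocount Smoothing weight `lambda` (>= 0).
#' @param base Logarithm base (2 = bits, the default).
#' @return Mutual information (non-negative).
#' @export
column_mi <- function(aln, groups, column, pseudocount = 0, base = 2) {
  stopifnot(inherits(aln, "protein_alignment"), pseudocount >= 0)
  if (!is.numeric(column) || column < 1 || column > ncol(aln$mat)) {
    stop("unknown column: ", column)
  }
  groups <- groups[aln$ids]
  labs <- sort(unique(groups))
  col <- aln$mat[, column]
  q_a <- overall_residue_freqs(aln)
  n_ai <- column_counts(col, groups, labs)
  mi_from_counts(n_ai, pseudocount, q_a, base)
}

overall_residue_freqs <- function(aln) {
  tab <- table(factor(aln$mat[aln$mat %in% AA20], levels = AA20))
  if (sum(tab) == 0) return(setNames(rep(1 / 20, 20), AA20))
  as.numeric(tab) / sum(tab)
}

#' Scan an alignment for specificity-determining positions
#'
#' Columns are scored by mutual information between residue and group label;
#' significance comes from `n_shuffles` permutations of the group labels
#' across sequences (the same permutation applied to every column within a
#' replicate): `Z = (MI - mean_shuffle) / sd_shuffle`.  Columns with more
#' than `max_gap_fraction` gaps are not scored.  The number of reported SDPs
#' is chosen by [bernoulli_cutoff()] on the ranked Z-scores; only columns
#' with `Z > 0` are ever selected.  Deterministic given `seed`.
#'
#' @param aln A `protein_alignment`.
#' @param groups Named character vector id -> group label (>= 2 groups, each
#'   with >= 2 sequences).
#' @param n_shuffles Number of label permutations (default 1000).
#' @param pseudocount Smoothing weight for [column_mi()] (default 1).
#' @param seed Integer seed.
#' @param max_gap_fraction Columns gappier than this are skipped.
#' @return An `sdp_result`: data frame `columns` (`column`, `mi`, `z`,
#'   `scored`), `b_curve`, `cutoff_L`, and `sdps` (selected column indices,
#'   ranked by Z).
#' @export
sdp_scan <- function(aln, groups, n_shuffles = 1000L, pseudocount = 1,
                     seed = 1L, max_gap_fraction = 0.1) {
  stopifnot(inherits(aln, "protein_alignment"))
  missing <- setdiff(aln$ids, names(groups))
  if (length(missing)) stop("no group for: ", paste(missing, collapse = ", "))
  groups <- groups[aln$ids]
  labs <- sort(unique(groups))
  if (length(labs) < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop("group(s) with a single sequence: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  n_col <- ncol(aln$mat)
  gap_frac <- colMeans(matrix(!(aln$mat %in% AA20), nrow = nrow(aln$mat)))
  scored <- gap_frac <= max_gap_fraction
  q_a <- overall_residue_freqs(aln)

  mi_cols <- function(g) {
    vapply(which(scored), function(j) {
      mi_from_counts(column_counts(aln$mat[, j], g, labs), pseudocount, q_a)
    }, numeric(1))
  }
  mi_obs <- mi_cols(groups)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # permute labels over the sorted id list so the null distribution (and the
  # Z-scores) do not depend on the row order of the alignment
  ids_sorted <- sort(aln$ids)
  base <- groups[ids_sorted]
  shuf <- matrix(NA_real_, n_shuffles, sum(scored))
  for (r in seq_len(n_shuffles)) {
    shuf[r, ] <- mi_cols(setNames(sample(base), ids_sorted)[aln$ids])
  }
  mu <- colMeans(shuf)
  sdev <- apply(shuf, 2, sd)
  z_scored <- ifelse(sdev > 0, (mi_obs - mu) / sdev, 0)

  cols <- data.frame(column = seq_len(n_col), mi = NA_real_, z = NA_real_,
                     scored = scored)
  cols$mi[scored] <- mi_obs
  cols$z[scored] <- z_scored

  ord <- order(-z_scored)
  bc <- bernoulli_cutoff(z_scored[ord])
  candidates <- which(scored)[ord]
  positive <- cols$z[candidates] > 0
  sdps <- candidates[seq_len(min(bc$cutoff_L, sum(positive)))]
  sdps <- sdps[cols$z[sdps] > 0]

  structure(list(columns = cols, b_curve = bc$b_curve, cutoff_L = bc$cutoff_L,
                 sdps = sdps, n_shuffles = n_shuffles, seed = seed),
            class = "sdp_result")
}

#' @export
print.sdp_result <- function(x, ...) {
  cat("SDP scan:", sum(x$columns$scored), "scored columns,",
      length(x$sdps), "SDP(s) selected (cutoff L =", x$cutoff_L, ")\n")
  if (length(x$sdps)) {
    sel <- x$columns[x$sdps, ]
    for (k in seq_len(nrow(sel))) {
      cat(sprintf("  column %d: MI = %.3f, Z = %.2f\n",
                  sel$column[k], sel$mi[k], sel$z[k]))
    }
  }
  invisible(x)
}

#' Bernoulli-estimator cutoff on ranked Z-scores
#'
#' For each candidate count `L`, `eps_L` is the null tail probability
#' `P(Z >= z_(L))` (standard normal by default) and
#' `B(L) = log10 P(Binomial(N, eps_L) >= L)`: the chance that at least `L`
#' of the `N` columns reach the `L`-th score by chance.  The selected cutoff
#' minimizes `B(L)`; ties go to the smallest `L`.
#'
#' @param z_sorted Z-scores sorted in decreasing order.
#' @param tail Function mapping a Z value to its null upper-tail
#'   probability (default `pnorm(z, lower.tail = FALSE)`).
#' @return List with `cutoff_L` and `b_curve` (data frame `L`, `z`, `eps`,
#'   `B`).
#' @export
bernoulli_cutoff <- function(z_sorted,
                             tail = function(z) pnorm(z, lower.tail = FALSE)) {
  if (!length(z_sorted)) stop("no scores supplied")
  if (is.unsorted(rev(z_sorted))) stop("z_sorted must be in decreasing order")
  N <- length(z_sorted)
  eps <- pmin(pmax(vapply(z_sorted, tail, numeric(1)), 0), 1)
  B <- vapply(seq_len(N), function(L) {
    pbinom(L - 1L, N, eps[L], lower.tail = FALSE, log.p = TRUE) / log(10)
  }, numeric(1))
  list(cutoff_L = which.min(B),   # which.min takes the first (smallest L) tie
       b_curve = data.frame(L = seq_len(N), z = z_sorted, eps = eps, B = B))
}

#' SDP report table
#'
#' One row per selected SDP, with the residue composition of each group and
#' per-reference-sequence positions (counting only that sequence's non-gap
#' columns), in the shape of an SDP report table.
#'
#' @param result An `sdp_result`.
#' @param aln The scanned `protein_alignment`.
#' @param groups The group assignment used in the scan.
#' @param reference_ids Sequences whose ungapped coordinates to report.
#' @return Data frame with rank, alignment column, MI, Z, B value, group
#'   residue summaries and reference positions.
#' @export
sdp_table <- function(result, aln, groups, reference_ids = character(0)) {
  stopifnot(inherits(result, "sdp_result"))
  groups <- groups[aln$ids]
  labs <- sort(unique(groups))
  sel <- result$sdps
  out <- data.frame(rank = seq_along(sel), column = sel,
                    mi = result$columns$mi[sel], z = result$columns$z[sel])
  ranked <- result$b_curve$L[match(round(result$columns$z[sel], 10),
                                   round(result$b_curve$z, 10))]
  out$B <- result$b_curve$B[ranked]
  for (lab in labs) {
    out[[paste0("residues_", lab)]] <- vapply(sel, function(j) {
      r <- aln$mat[groups == lab, j]
      paste(sort(unique(r[r %in% AA20])), collapse = "/")
    }, character(1))
  }
  for (id in reference_ids) {
    pos_map <- cumsum(aln$mat[id, ] != "-")
    out[[paste0("pos_", id)]] <- vapply(sel, function(j) {
      if (aln$mat[id, j] == "-") NA_character_
      else paste0(pos_map[j], aln$mat[id, j])
    }, character(1))
  }
  out
}
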