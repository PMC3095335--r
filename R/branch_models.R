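# Branch models: a single shared omega (one-ratio) versus an independent
# omega per branch (free-ratio), compared by LRT to detect lineages under
# positive selection.

branch_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  ifelse(child <= n_tip, tree$tip.label[child], paste0("node", child))
}

#' Fit a branch model (one-ratio or free-ratio)
#'
#' The one-ratio model shares a single omega across all branches (it is the
#' M0 site model); the free-ratio model gives every branch its own omega.
#' When `mode = "free_ratio"` the one-ratio model is fitted too (unless
#' supplied via `settings$null_fit`) and the LRT between them is returned.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `phylo` tree matching the alignment ids.
#' @param mode `"one_ratio"` or `"free_ratio"`.
#' @param settings As in [fit_site_model()]; additionally `null_fit` (a
#'   previous one-ratio `branch_model_fit` to reuse).
#' @return A `branch_model_fit`: `mode`, `lnL`, `kappa`, `omega_by_branch`
#'   (named by the child node of each postorder edge), `flagged_branches`
#'   (omega > 1), `unidentifiable_branches` (branch length at the zero
#'   bound, where omega carries no information), `tree`, `n_params`, and for
#'   free-ratio fits `lrt` against one-ratio.
#' @export
fit_branch_model <- function(aln, tree, mode = c("one_ratio", "free_ratio"),
                             settings = list()) {
  mode <- match.arg(mode)
  null_fit <- settings$null_fit
  settings$null_fit <- NULL
  st <- default_fit_settings(settings)

  if (mode == "one_ratio") {
    m0 <- fit_site_model(aln, tree, "M0", settings = st[
      intersect(names(st), c("seed", "n_starts", "maxit", "factr",
                             "freq_mode", "codon_freqs"))])
    E <- nrow(m0$tree$edge)
    omega <- m0$classes$omega[1]
    fit <- list(mode = "one_ratio", model_name = "one_ratio", lnL = m0$lnL,
                kappa = m0$kappa,
                omega_by_branch = setNames(rep(omega, E), branch_labels(m0$tree)),
                flagged_branches = character(0),
                unidentifiable_branches =
                  branch_labels(m0$tree)[m0$tree$edge.length <= 1e-6],
                tree = m0$tree, codon_freqs = m0$codon_freqs,
                n_params = m0$n_params)
    if (omega > 1) fit$flagged_branches <- names(fit$omega_by_branch)
    return(structure(fit, class = "branch_model_fit"))
  }

  if (is.null(null_fit)) {
    null_fit <- fit_branch_model(aln, tree, "one_ratio", settings = st[
      intersect(names(st), c("seed", "n_starts", "maxit", "factr",
                             "freq_mode", "codon_freqs"))])
  }
  prep <- prepare_pruning(aln, tree)
  E <- nrow(prep$edge)
  pi <- null_fit$codon_freqs

  # par = (log t per edge, log kappa, log omega per edge)
  par0 <- c(log(pmin(pmax(null_fit$tree$edge.length, 1e-6), 25)),
            log(null_fit$kappa),
            rep(log(max(null_fit$omega_by_branch[1], 1e-3)), E))
  lower <- c(rep(log(1e-7), E), log(0.05), rep(log(1e-4), E))
  upper <- c(rep(log(30), E), log(50), rep(log(30), E))

  negll <- function(par) {
    edge_len <- exp(par[seq_len(E)])
    kappa <- exp(par[E + 1L])
    omegas <- exp(par[(E + 2L):(2L * E + 1L)])
    val <- tryCatch({
      uo <- unique(omegas)
      eig_by_omega <- lapply(uo, function(om) gy94_eigen(kappa, om, pi))
      eigs <- eig_by_omega[match(omegas, uo)]
      ll <- cpp_branch_loglik(prep$edge, edge_len, prep$n_node, prep$tips,
                              eigs, pi)
      sum(prep$w * ll)
    }, error = function(e) NA_real_)
    if (!is.finite(val)) 1e12 else -val
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(st$seed)
  best <- NULL
  for (s in seq_len(st$n_starts)) {
    p_start <- if (s == 1L) par0 else {
      pmin(pmax(par0 + stats::rnorm(length(par0), 0, 0.3), lower), upper)
    }
    opt <- tryCatch(
      optim(p_start, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = st$maxit, factr = st$factr)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e12) {
    stop("free-ratio optimization failed to reach a finite likelihood")
  }

  edge_len <- exp(best$par[seq_len(E)])
  kappa <- exp(best$par[E + 1L])
  omegas <- exp(best$par[(E + 2L):(2L * E + 1L)])
  fitted_tree <- prep$tree
  fitted_tree$edge.length <- edge_len
  labs <- branch_labels(fitted_tree)
  unident <- edge_len <= 1e-6
  fit <- structure(list(
    mode = "free_ratio", model_name = "free_ratio",
    lnL = -best$value, kappa = kappa,
    omega_by_branch = setNames(omegas, labs),
    flagged_branches = labs[omegas > 1 & !unident],
    unidentifiable_branches = labs[unident],
    tree = fitted_tree, codon_freqs = pi,
    n_params = 2L * E + 1L
  ), class = "branch_model_fit")
  fit$lrt <- likelihood_ratio_test(null_fit, fit)
  fit
}

#' @export
print.branch_model_fit <- function(x, ...) {
  cat(sprintf("branch model (%s): lnL = %.4f, kappa = %.3f\n",
              x$mode, x$lnL, x$kappa))
  if (x$mode == "free_ratio") {
    cat("  branches with omega > 1:",
        if (length(x$flagged_branches)) paste(x$flagged_branches, collapse = ", ")
        else "none", "\n")
    if (!is.null(x$lrt)) {
      cat(sprintf("  LRT vs one-ratio: 2dl = %.2f, df = %d, p = %.3g\n",
                  x$lrt$two_delta_l, x$lrt$df, x$lrt$p_value))
    }
  }
  invisible(x)
}

#' Annotated Newick with flagged branches
#'
#' Writes the fitted tree with `#flagged` appended to the label of every
#' branch whose omega exceeds 1 (the usual red-branch convention of
#' free-ratio figures, as text).
#'
#' @param fit A free-ratio `branch_model_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flagged_newick <- function(fit, path) {
  stopifnot(inherits(fit, "branch_model_fit"))
  tree <- fit$tree
  labs <- branch_labels(tree)
  n_tip <- length(tree$tip.label)
  flag <- labs %in% fit$flagged_branches
  child <- tree$edge[, 2]
  tip_flag <- child[flag & child <= n_tip]
  node_flag <- child[flag & child > n_tip]
  tree$tip.label[tip_flag] <- paste0(tree$tip.label[tip_flag], "#flagged")
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  tree$node.label[node_flag - n_tip] <-
    paste0(tree$node.label[node_flag - n_tip], "#flagged")
  ape::write.tree(tree, file = path)
  invisible(path)
}
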