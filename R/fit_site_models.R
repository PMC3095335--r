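# Maximum-likelihood fitting of codon site models (M0, M3, M7, M8) by
# Felsenstein pruning over the compiled kernel, with NEB site posteriors and
# likelihood-ratio tests between nested models.

logsumexp_rows <- function(A) {
  mx <- do.call(pmax, c(as.data.frame(A), list(na.rm = FALSE)))
  mx + log(rowSums(exp(A - mx)))
}

# Alignment + tree -> pruning-ready structure with site-pattern compression.
prepare_pruning <- function(aln, tree) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "phylo"))
  extra_tip <- setdiff(tree$tip.label, aln$ids)
  extra_aln <- setdiff(aln$ids, tree$tip.label)
  if (length(extra_tip) || length(extra_aln)) {
    stop("tree/alignment mismatch; only in tree: {",
         paste(extra_tip, collapse = ","), "}, only in alignment: {",
         paste(extra_aln, collapse = ","), "}")
  }
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  states <- matrix(match(aln$codons, sense_codons()), nrow = nrow(aln$codons))
  states[is.na(states)] <- 0L
  states <- states[match(tree$tip.label, aln$ids), , drop = FALSE]
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pattern_of_site <- match(key, key[first])
  tips <- states[, first, drop = FALSE]
  list(tree = tree, edge = tree$edge, n_node = n_tip + tree$Nnode,
       n_tip = n_tip, tips = tips,
       w = as.numeric(table(factor(pattern_of_site, levels = seq_len(sum(first))))),
       pattern_of_site = pattern_of_site, n_sites = ncol(states))
}

# per-pattern class log-likelihood matrix (m x K) for a class mixture
class_loglik_matrix <- function(prep, edge_len, kappa, classes, pi) {
  eigs <- lapply(classes$omega, function(om) gy94_eigen(kappa, om, pi))
  cpp_class_loglik(prep$edge, edge_len, prep$n_node, prep$tips, eigs, pi)
}

mixture_loglik <- function(prep, edge_len, kappa, classes, pi) {
  A <- class_loglik_matrix(prep, edge_len, kappa, classes, pi)
  A2 <- sweep(A, 2, log(classes$prop), "+")
  site <- logsumexp_rows(A2)
  list(total = sum(prep$w * site), pattern_ll = site, class_ll = A)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# model-specific parameterizations on an unconstrained-ish bounded scale
site_model_spec <- function(which, k_classes = 3L) {
  switch(which,
    M0 = list(
      init = log(0.2),
      lower = log(1e-4), upper = log(30),
      classes = function(par) data.frame(prop = 1, omega = exp(par)),
      describe = function(par) list(omega = exp(par)),
      n_free = 1L),
    M3 = list(
      init = c(seq(log(0.05), log(1.5), length.out = k_classes),
               rep(0, k_classes - 1L)),
      lower = c(rep(log(1e-4), k_classes), rep(-20, k_classes - 1L)),
      upper = c(rep(log(30), k_classes), rep(20, k_classes - 1L)),
      classes = function(par) {
        data.frame(prop = softmax(c(par[(k_classes + 1):(2 * k_classes - 1)], 0)),
                   omega = exp(par[seq_len(k_classes)]))
      },
      describe = function(par) list(),
      n_free = 2L * k_classes - 1L),
    M7 = list(
      init = c(log(0.8), log(1.5)),
      lower = rep(log(0.005), 2), upper = rep(log(50), 2),
      classes = function(par) beta_omega_classes(exp(par[1]), exp(par[2])),
      describe = function(par) list(p = exp(par[1]), q = exp(par[2])),
      n_free = 2L),
    M8 = list(
      init = c(log(0.8), log(1.5), stats::qlogis(0.9), log(1)),
      lower = c(rep(log(0.005), 2), -15, -12),
      upper = c(rep(log(50), 2), 15, log(29)),
      classes = function(par) {
        p0 <- stats::plogis(par[3])
        ws <- 1 + exp(par[4])
        bc <- beta_omega_classes(exp(par[1]), exp(par[2]))
        rbind(data.frame(prop = p0 * bc$prop, omega = bc$omega),
              data.frame(prop = 1 - p0, omega = ws))
      },
      describe = function(par) list(p = exp(par[1]), q = exp(par[2]),
                                    p0 = stats::plogis(par[3]),
                                    omega_s = 1 + exp(par[4])),
      n_free = 4L),
    stop("unknown site model: ", which)
  )
}

default_fit_settings <- function(settings) {
  defaults <- list(seed = 1L, n_starts = 2L, maxit = 500L, factr = 1e8,
                   freq_mode = "F3x4", codon_freqs = NULL, k_classes = 3L,
                   init_fit = NULL)
  unknown <- setdiff(names(settings), names(defaults))
  if (length(unknown)) stop("unknown settings: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, settings)
}

#' Fit a codon site model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over all branch lengths, kappa and
#' the model's omega-distribution parameters.  M0 has one omega; M3 a
#' discrete mixture of `k_classes` omegas; M7 a beta(p, q) on (0, 1)
#' discretized into 10 equal-probability classes; M8 adds to M7 a class with
#' omega >= 1 and weight `1 - p0`.  Multi-start bounded quasi-Newton
#' optimization, deterministic given `settings$seed`.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `phylo` tree whose tips match the alignment ids; any branch
#'   lengths present are used as starting values only.
#' @param model One of `"M0"`, `"M3"`, `"M7"`, `"M8"`.
#' @param settings Optional list: `seed`, `n_starts`, `maxit`, `factr`
#'   (optimizer tolerance), `freq_mode` (`"F3x4"`, `"F1x4"`, `"equal"`),
#'   `codon_freqs` (explicit frequencies override), `k_classes` (M3),
#'   `init_fit` (a previous `site_model_fit` to warm-start from, e.g. the M7
#'   fit when fitting M8 -- this also guarantees the nested-model likelihood
#'   ordering).
#' @return A `site_model_fit` with elements `model_name`, `lnL`, `kappa`,
#'   `classes` (mixture data frame), `beta_params`, `tree` (fitted branch
#'   lengths, postorder), `codon_freqs`, `n_params`, `site_posteriors`
#'   (site x class NEB posterior matrix) and `pss` (per-site posterior of
#'   the omega > 1 classes).
#' @export
fit_site_model <- function(aln, tree, model = c("M0", "M3", "M7", "M8"),
                           settings = list()) {
  model <- match.arg(model)
  st <- default_fit_settings(settings)
  prep <- prepare_pruning(aln, tree)
  E <- nrow(prep$edge)
  pi <- if (!is.null(st$codon_freqs)) st$codon_freqs
        else codon_frequencies(aln, st$freq_mode)
  spec <- site_model_spec(model, st$k_classes)

  t0 <- prep$tree$edge.length
  if (is.null(t0) || any(!is.finite(t0))) t0 <- rep(0.2, E)
  t0 <- pmin(pmax(t0, 1e-4), 20)
  par0 <- c(log(t0), log(2), spec$init)

  # warm start from a nested / previous fit on the same topology
  extra_starts <- list()
  if (!is.null(st$init_fit)) {
    f <- st$init_fit
    par0[seq_len(E)] <- log(pmin(pmax(f$tree$edge.length, 1e-6), 25))
    par0[E + 1L] <- log(f$kappa)
    if (model == "M3" && f$model_name == "M0") {
      k <- st$k_classes
      par0[(E + 2L):(E + 1L + k)] <- log(f$classes$omega[1] *
                                           seq(0.999, 1.001, length.out = k))
    } else if (model == "M8" && f$model_name == "M7") {
      par0[E + 2L] <- log(f$beta_params$p)
      par0[E + 3L] <- log(f$beta_params$q)
      par0[E + 4L] <- 15      # p0 -> ~1: reduces to the M7 fit
      par0[E + 5L] <- log(1)
      # second deterministic start with the selection class switched on,
      # since the replica start sits on a flat boundary
      sel_start <- par0
      sel_start[E + 4L] <- stats::qlogis(0.9)
      sel_start[E + 5L] <- log(2)
      extra_starts <- list(sel_start)
    } else if (model == f$model_name && model %in% c("M7", "M8")) {
      par0[E + 2L] <- log(f$beta_params$p)
      par0[E + 3L] <- log(f$beta_params$q)
      if (model == "M8") {
        par0[E + 4L] <- stats::qlogis(min(max(f$beta_params$p0, 1e-6), 1 - 1e-6))
        par0[E + 5L] <- log(max(f$beta_params$omega_s - 1, 1e-5))
      }
    }
  }

  lower <- c(rep(log(1e-7), E), log(0.05), spec$lower)
  upper <- c(rep(log(30), E), log(50), spec$upper)
  par0 <- pmin(pmax(par0, lower), upper)

  negll <- function(par) {
    edge_len <- exp(par[seq_len(E)])
    kappa <- exp(par[E + 1L])
    classes <- spec$classes(par[-seq_len(E + 1L)])
    val <- tryCatch(
      mixture_loglik(prep, edge_len, kappa, classes, pi)$total,
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e12 else -val
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(st$seed)
  starts <- c(list(par0), extra_starts)
  for (s in seq_len(max(st$n_starts - 1L, 0L))) {
    starts <- c(starts, list(
      pmin(pmax(par0 + stats::rnorm(length(par0), 0, 0.3), lower), upper)))
  }
  best <- NULL
  for (p_start in starts) {
    opt <- tryCatch(
      optim(p_start, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = st$maxit, factr = st$factr)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e12) {
    stop("site-model optimization failed to reach a finite likelihood (",
         model, ")")
  }

  par <- best$par
  edge_len <- exp(par[seq_len(E)])
  kappa <- exp(par[E + 1L])
  classes <- spec$classes(par[-seq_len(E + 1L)])
  ll <- mixture_loglik(prep, edge_len, kappa, classes, pi)

  # NEB posteriors: P(class k | site) = p_k L_hk / sum_j p_j L_hj
  A2 <- sweep(ll$class_ll, 2, log(classes$prop), "+")
  post_pattern <- exp(A2 - ll$pattern_ll)
  post <- post_pattern[prep$pattern_of_site, , drop = FALSE]
  sel <- classes$omega > 1
  pss <- if (any(sel)) rowSums(post[, sel, drop = FALSE]) else rep(0, prep$n_sites)

  fitted_tree <- prep$tree
  fitted_tree$edge.length <- edge_len
  structure(list(
    model_name = model,
    lnL = ll$total,
    kappa = kappa,
    classes = classes[order(classes$omega), , drop = FALSE],
    beta_params = spec$describe(par[-seq_len(E + 1L)]),
    tree = fitted_tree,
    codon_freqs = pi,
    n_params = E + 1L + spec$n_free,
    site_posteriors = post,
    pss = pss,
    convergence = best$convergence,
    settings = st
  ), class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, kappa = %.3f, %d free parameters\n",
              x$model_name, x$lnL, x$kappa, x$n_params))
  cls <- x$classes
  cat("  omega distribution:",
      paste(sprintf("%.2f%% sites: omega = %.3f", 100 * cls$prop, cls$omega),
            collapse = "; "), "\n")
  invisible(x)
}

#' Per-site log-likelihoods under a fixed codon model
#'
#' Felsenstein pruning with the branch lengths carried by `tree`; mixture
#' models sum per-site class likelihoods weighted by class proportions.  Gap
#' codons are treated as missing data.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `phylo` with branch lengths (ignored when the alignment has
#'   a single sequence).
#' @param model A [codon_model()].
#' @return List with `site_loglik` (per site), `lnL` (their sum) and
#'   `class_loglik` (site x class matrix).
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  stopifnot(inherits(model, "codon_model"))
  pi <- model$codon_freqs
  if (length(aln$ids) == 1L) {
    idx <- match(aln$codons[1, ], sense_codons())
    site <- ifelse(is.na(idx), 0, log(pi[idx]))
    return(list(site_loglik = site, lnL = sum(site),
                class_loglik = matrix(site, ncol = 1)))
  }
  prep <- prepare_pruning(aln, tree)
  if (is.null(prep$tree$edge.length)) stop("tree must carry branch lengths")
  ll <- mixture_loglik(prep, prep$tree$edge.length, model$kappa,
                       model$omega_classes, pi)
  list(site_loglik = ll$pattern_ll[prep$pattern_of_site],
       lnL = ll$total,
       class_loglik = ll$class_ll[prep$pattern_of_site, , drop = FALSE])
}

#' BEB-lite site posteriors for an M8 fit
#'
#' A lightweight Bayes-empirical-Bayes variant: instead of plugging in the
#' point estimates of the selection-class parameters, the NEB posterior of
#' the omega > 1 class is averaged over a grid of (p0, omega_s) values
#' weighted by the data likelihood at each grid point (branch lengths,
#' kappa and the beta shape parameters stay at their MLEs).  This damps the
#' optimism of plain NEB when the selection-class parameters are poorly
#' determined.  Exploratory; the NEB posteriors in the fit are the primary
#' contract.
#'
#' @param fit An M8 `site_model_fit`.
#' @param aln The `codon_alignment` the fit was computed from.
#' @param grid_size Grid resolution per parameter (default 10).
#' @return Numeric vector: per-site posterior of the omega > 1 class,
#'   averaged over the grid.
#' @export
beb_lite_posteriors <- function(fit, aln, grid_size = 10L) {
  stopifnot(inherits(fit, "site_model_fit"))
  if (fit$model_name != "M8") stop("BEB-lite is defined for M8 fits")
  prep <- prepare_pruning(aln, fit$tree)
  edge_len <- fit$tree$edge.length
  bp <- fit$beta_params
  p0_grid <- seq(0.05, 0.995, length.out = grid_size)
  ws_grid <- exp(seq(log(1.001), log(15), length.out = grid_size))
  bc <- beta_omega_classes(bp$p, bp$q)

  # class likelihoods depend on omega_s only through the last class
  posts <- vector("list", grid_size)
  for (j in seq_len(grid_size)) {
    classes <- rbind(data.frame(prop = bc$prop / sum(bc$prop), omega = bc$omega),
                     data.frame(prop = 1, omega = ws_grid[j]))
    A <- class_loglik_matrix(prep, edge_len, fit$kappa, classes,
                             fit$codon_freqs)
    posts[[j]] <- A
  }
  weights <- numeric(0); post_list <- list()
  for (i in seq_len(grid_size)) {
    for (j in seq_len(grid_size)) {
      props <- c(p0_grid[i] * bc$prop, 1 - p0_grid[i])
      A2 <- sweep(posts[[j]], 2, log(props), "+")
      site_ll <- logsumexp_rows(A2)
      lnl <- sum(prep$w * site_ll)
      sel_post <- exp(A2[, ncol(A2)] - site_ll)
      weights <- c(weights, lnl)
      post_list[[length(post_list) + 1L]] <- sel_post
    }
  }
  w <- exp(weights - max(weights))
  w <- w / sum(w)
  avg <- Reduce(`+`, Map(`*`, post_list, w))
  avg[prep$pattern_of_site]
}

lrt_nested_pairs <- list(c("M0", "M3"), c("M7", "M8"),
                         c("one_ratio", "free_ratio"))

#' Likelihood-ratio test between nested fits
#'
#' @param null_fit,alt_fit Fits from [fit_site_model()] or
#'   [fit_branch_model()]; the null must be nested in the alternative
#'   (M0 in M3, M7 in M8, one-ratio in free-ratio).
#' @param tol Allowed optimizer slack: `lnL(alt)` below `lnL(null) - tol` is
#'   treated as an optimization failure and raises an error.
#' @return List with `two_delta_l`, `df` and `p_value` (chi-squared upper
#'   tail).
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit, tol = 0.01) {
  pair <- c(null_fit$model_name, alt_fit$model_name)
  ok <- any(vapply(lrt_nested_pairs, function(p) all(p == pair), logical(1)))
  if (!ok) {
    stop("models are not a supported nested pair: ", pair[1], " vs ", pair[2])
  }
  two_delta <- 2 * (alt_fit$lnL - null_fit$lnL)
  if (two_delta < -2 * tol) {
    stop("alternative fit has lower likelihood than the null (2dl = ",
         signif(two_delta, 4), "); optimization likely failed")
  }
  two_delta <- max(two_delta, 0)
  df <- as.integer(alt_fit$n_params - null_fit$n_params)
  if (df <= 0) stop("alternative must have more free parameters than the null")
  list(two_delta_l = two_delta, df = df,
       p_value = pchisq(two_delta, df = df, lower.tail = FALSE))
}

#' Positively selected sites from NEB posteriors
#'
#' Sites whose posterior probability of belonging to an omega > 1 class
#' reaches `report_floor` are listed; those reaching `high` are starred
#' (the conventional `*` of site-model report tables).
#'
#' @param fit A `site_model_fit`.
#' @param high Posterior for a starred call (default 0.95).
#' @param report_floor Minimum posterior to report at all (default 0.7).
#' @return Data frame with `site`, `posterior`, `starred`; empty when the
#'   fit has no omega > 1 class.
#' @export
positively_selected_sites <- function(fit, high = 0.95, report_floor = 0.7) {
  stopifnot(inherits(fit, "site_model_fit"))
  empty <- data.frame(site = integer(0), posterior = numeric(0),
                      starred = logical(0))
  if (!any(fit$classes$omega > 1)) return(empty)
  keep <- which(fit$pss >= report_floor)
  if (!length(keep)) return(empty)
  data.frame(site = keep, posterior = fit$pss[keep],
             starred = fit$pss[keep] >= high)
}
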