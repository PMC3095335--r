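# GY94-style codon substitution model: 61 sense-codon states, rate to a
# single-nucleotide neighbour j proportional to pi_j, multiplied by kappa for
# transitions and by omega for nonsynonymous changes.  The generator is
# scaled so branch lengths are expected substitutions per codon.

#' Codon substitution model specification
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega_classes Data frame with columns `prop` and `omega`: the
#'   site-class mixture (proportions must sum to 1, omegas >= 0).
#' @param codon_freqs Frequencies over the 61 sense codons (summing to 1), in
#'   [sense_codons()] order; `NULL` for equal frequencies.
#' @param beta_params Optional named list with `p` and `q` (and for M8-style
#'   models `p0` and `omega_s`) recording how the classes were derived.
#' @param freq_mode How `codon_freqs` were obtained: `"equal"`, `"F1x4"` or
#'   `"F3x4"`.
#' @return An object of class `codon_model`.
#' @export
codon_model <- function(kappa, omega_classes, codon_freqs = NULL,
                        beta_params = NULL, freq_mode = "equal") {
  stopifnot(is.numeric(kappa), kappa > 0)
  omega_classes <- as.data.frame(omega_classes)
  stopifnot(all(c("prop", "omega") %in% names(omega_classes)))
  if (abs(sum(omega_classes$prop) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (any(omega_classes$omega < 0)) stop("omega values must be >= 0")
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / 61, 61)
  if (length(codon_freqs) != 61L) stop("codon_freqs must have 61 entries")
  if (abs(sum(codon_freqs) - 1) > 1e-8) stop("codon_freqs must sum to 1")
  structure(list(kappa = kappa, omega_classes = omega_classes,
                 codon_freqs = as.numeric(codon_freqs),
                 beta_params = beta_params, freq_mode = freq_mode),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat("codon_model: kappa =", signif(x$kappa, 4), "\n")
  for (k in seq_len(nrow(x$omega_classes))) {
    cat(sprintf("  class %d: p = %.4f, omega = %.4f\n", k,
                x$omega_classes$prop[k], x$omega_classes$omega[k]))
  }
  invisible(x)
}

#' GY94 codon rate matrix
#'
#' Off-diagonal rate from codon i to a single-nucleotide neighbour j is
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]`; codons differing at
#' more than one position get rate 0.  The generator is scaled so the
#' expected substitution rate at stationarity is 1 per codon.
#'
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param codon_freqs Stationary codon frequencies (61, summing to 1);
#'   `NULL` for equal.
#' @return 61x61 generator matrix with codon dimnames; the stationary
#'   frequencies are attached as attribute `"pi"`.
#' @export
codon_rate_matrix <- function(kappa, omega, codon_freqs = NULL) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("omega must be >= 0")
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / 61, 61)
  stopifnot(length(codon_freqs) == 61L, abs(sum(codon_freqs) - 1) < 1e-8)
  cod <- sense_codons()
  nbr <- codon_neighbours()
  Q <- matrix(0, 61, 61, dimnames = list(cod, cod))
  rate <- codon_freqs[nbr$jj + 1L] *
    ifelse(nbr$ts == 1L, kappa, 1) *
    ifelse(nbr$syn == 1L, 1, omega)
  Q[cbind(nbr$ii + 1L, nbr$jj + 1L)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(codon_freqs * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (no substitutions possible)")
  Q <- Q / scale
  attr(Q, "pi") <- codon_freqs
  Q
}

#' Transition probability matrix
#'
#' `P(t) = exp(Qt)` via the symmetric eigendecomposition available for
#' reversible generators built by [codon_rate_matrix()].
#'
#' @param Q Generator from [codon_rate_matrix()] (carries its stationary
#'   frequencies as attribute `"pi"`).
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @return Row-stochastic 61x61 matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("branch length must be >= 0")
  pi <- attr(Q, "pi")
  if (is.null(pi)) stop("Q must carry its stationary frequencies (attribute 'pi')")
  sp <- sqrt(pi)
  B <- sweep(sweep(unclass(Q), 1, sp, "*"), 2, sp, "/")
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  # P = diag(1/sp) V diag(exp(lambda t)) V' diag(sp)
  V <- eg$vectors
  P <- sweep(V, 1, sp, "/") %*% diag(exp(eg$values * t)) %*% sweep(t(V), 2, sp, "*")
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

# fast eigen path used by the fitting and simulation code
gy94_eigen <- function(kappa, omega, pi) {
  nbr <- codon_neighbours()
  cpp_gy94_eigen(pi, kappa, omega, nbr$ii, nbr$jj, nbr$ts, nbr$syn)
}

gy94_pmat <- function(eig, t) cpp_pmat(eig, t)

#' Empirical codon frequencies (F3x4 / F1x4 / equal)
#'
#' F3x4 multiplies position-specific nucleotide frequencies observed in the
#' alignment; F1x4 uses a single shared nucleotide distribution.  Stop codons
#' are excluded and the result renormalized over the 61 sense codons.  A
#' small floor keeps unobserved codons at nonzero frequency.
#'
#' @param aln A `codon_alignment`.
#' @param mode `"F3x4"`, `"F1x4"` or `"equal"`.
#' @return Numeric vector of 61 frequencies in [sense_codons()] order.
#' @export
codon_frequencies <- function(aln, mode = c("F3x4", "F1x4", "equal")) {
  mode <- match.arg(mode)
  if (mode == "equal") return(rep(1 / 61, 61))
  stopifnot(inherits(aln, "codon_alignment"))
  cods <- aln$codons[aln$codons != "---" & !grepl("N", aln$codons)]
  if (!length(cods)) stop("no ungapped codons in alignment")
  nucs <- c("T", "C", "A", "G")
  cod <- sense_codons()
  if (mode == "F1x4") {
    f <- table(factor(unlist(strsplit(cods, "")), levels = nucs))
    f <- (f + 0.5) / sum(f + 0.5)
    pi <- f[substr(cod, 1, 1)] * f[substr(cod, 2, 2)] * f[substr(cod, 3, 3)]
  } else {
    fpos <- lapply(1:3, function(p) {
      f <- table(factor(substr(cods, p, p), levels = nucs))
      (f + 0.5) / sum(f + 0.5)
    })
    pi <- fpos[[1]][substr(cod, 1, 1)] * fpos[[2]][substr(cod, 2, 2)] *
      fpos[[3]][substr(cod, 3, 3)]
  }
  pi <- pmax(as.numeric(pi), 1e-10)
  pi / sum(pi)
}

#' Discretize a beta omega-distribution into equal-probability classes
#'
#' Class omega values are the beta inverse-CDF at the bin medians
#' `(2k + 1) / (2 n_classes)`.
#'
#' @param p,q Beta shape parameters.
#' @param n_classes Number of classes (default 10).
#' @return Data frame with `prop` and `omega`.
#' @export
beta_omega_classes <- function(p, q, n_classes = 10L) {
  stopifnot(p > 0, q > 0, n_classes >= 1L)
  k <- seq_len(n_classes) - 1L
  data.frame(prop = rep(1 / n_classes, n_classes),
             omega = qbeta((2 * k + 1) / (2 * n_classes), p, q))
}
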