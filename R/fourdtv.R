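# 4DTv: transversion proportion at third positions of conserved
# fourfold-degenerate codons, used to date paralog pairs.  The statistic is
# the raw proportion (no substitution-model correction), which runs from 0
# for recent duplicates to ~0.5 at saturation.

#' Conserved fourfold-degenerate sites of a codon-aligned pair
#'
#' A codon column qualifies when neither row is a gap or ambiguous, both
#' codons encode the same amino acid, and both belong to a fourfold-degenerate
#' codon box (third position fully degenerate under the standard code).
#'
#' @param aln A `codon_alignment` with exactly two rows.
#' @return Integer vector of qualifying codon-column indices (1-based).
#' @export
conserved_4d_sites <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (nrow(aln$codons) != 2L) stop("expected exactly two sequences")
  a <- aln$codons[1, ]; b <- aln$codons[2, ]
  ok <- a != "---" & b != "---" & !grepl("[^ACGT]", a) & !grepl("[^ACGT]", b)
  ff <- fourfold_prefixes()
  ok <- ok & substr(a, 1, 2) %in% ff & substr(b, 1, 2) %in% ff
  ok[ok] <- translate_codon(a[ok]) == translate_codon(b[ok])
  which(ok)
}

#' 4DTv distance of a paralog pair
#'
#' @param aln A `codon_alignment` with exactly two rows (use [d4dtv_table()]
#'   for more).
#' @return An object of class `fourdtv`: list with `d4dtv` (proportion, `NA`
#'   when no fourfold sites exist), `n_4d_sites`, `n_transversions` and
#'   `site_positions`.
#' @export
d4dtv <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (nrow(aln$codons) > 2L) {
    stop("alignment has >2 sequences; use d4dtv_table() for pairwise tables")
  }
  sites <- conserved_4d_sites(aln)
  third_a <- substr(aln$codons[1, sites], 3, 3)
  third_b <- substr(aln$codons[2, sites], 3, 3)
  ntv <- sum(is_transversion(third_a, third_b))
  structure(list(
    d4dtv = if (length(sites)) ntv / length(sites) else NA_real_,
    n_4d_sites = length(sites),
    n_transversions = ntv,
    site_positions = sites
  ), class = "fourdtv")
}

#' @export
print.fourdtv <- function(x, ...) {
  if (is.na(x$d4dtv)) {
    cat("4DTv: undefined (no conserved fourfold-degenerate sites)\n")
  } else {
    cat(sprintf("4DTv = %.3f (%d transversions / %d fourfold sites)\n",
                x$d4dtv, x$n_transversions, x$n_4d_sites))
  }
  invisible(x)
}

#' Pairwise 4DTv table
#'
#' One row per requested pair, in the shape of a paralog-dating report table.
#'
#' @param aln A `codon_alignment` with the sequences of interest.
#' @param pairs Two-column character matrix or data frame of id pairs, or
#'   `NULL` for all pairs.
#' @return Data frame with columns `id_a`, `id_b`, `n_4d_sites` and `d4dtv`
#'   (rounded to 3 decimals).
#' @export
d4dtv_table <- function(aln, pairs = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(pairs)) {
    if (length(aln$ids) < 2L) stop("need at least two sequences for all-pairs mode")
    pairs <- t(combn(aln$ids, 2L))
  }
  pairs <- as.matrix(pairs)
  if (length(pairs) && ncol(pairs) != 2L) stop("pairs must have two columns")
  out <- data.frame(id_a = character(0), id_b = character(0),
                    n_4d_sites = integer(0), d4dtv = numeric(0),
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    ids <- as.character(pairs[r, ])
    bad <- setdiff(ids, aln$ids)
    if (length(bad)) stop("unknown sequence id: ", bad[1])
    sub <- codon_alignment(codon_rows(aln)[ids], check_stops = FALSE)
    res <- d4dtv(sub)
    out[r, c("id_a", "id_b")] <- ids
    out$n_4d_sites[r] <- res$n_4d_sites
    out$d4dtv[r] <- round(res$d4dtv, 3)
  }
  out
}
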