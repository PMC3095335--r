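# Genetic-code lookup tables used across the package.  The standard code
# comes from Biostrings; everything else (sense-codon ordering, fourfold
# boxes, single-nucleotide neighbour lists) is derived from it once and
# memoised.

#' Sense codons of the standard genetic code
#'
#' The 61 stop-free codons, in the fixed order used for all rate matrices,
#' codon frequency vectors and simulator state indices in this package.
#'
#' @return Character vector of 61 codons.
#' @export
#' @examples
#' head(sense_codons())
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# codon -> amino acid for sense codons, in sense_codons() order
codon_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Prefixes (first two codon positions) whose third position is fully
# degenerate: all four completions encode the same amino acid.
fourfold_prefixes <- function() {
  if (!is.null(.seldiv_cache$ff_prefix)) return(.seldiv_cache$ff_prefix)
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1, 2))
  keep <- vapply(pre, function(p) {
    aa <- gc[paste0(p, c("T", "C", "A", "G"))]
    all(aa != "*") && length(unique(aa)) == 1L
  }, logical(1))
  .seldiv_cache$ff_prefix <- pre[keep]
  .seldiv_cache$ff_prefix
}

is_purine <- function(x) x %in% c("A", "G")

is_transversion <- function(a, b) is_purine(a) != is_purine(b)

# Neighbour table of the 61x61 codon space: ordered pairs (i, j) differing at
# exactly one nucleotide, with transition and synonymy flags.  0-based for
# the C++ kernel.
codon_neighbours <- function() {
  if (!is.null(.seldiv_cache$nbr)) return(.seldiv_cache$nbr)
  cod <- sense_codons()
  aa <- codon_aa()
  n <- length(cod)
  mat <- do.call(rbind, strsplit(cod, ""))
  ii <- jj <- ts <- syn <- integer(0)
  for (i in seq_len(n)) {
    diffs <- sweep(mat, 2, mat[i, ], FUN = "!=")
    ndiff <- rowSums(diffs)
    js <- which(ndiff == 1L)
    for (j in js) {
      pos <- which(diffs[j, ])
      a <- mat[i, pos]; b <- mat[j, pos]
      ii <- c(ii, i - 1L); jj <- c(jj, j - 1L)
      ts <- c(ts, as.integer(!is_transversion(a, b)))
      syn <- c(syn, as.integer(aa[i] == aa[j]))
    }
  }
  .seldiv_cache$nbr <- list(ii = ii, jj = jj, ts = ts, syn = syn)
  .seldiv_cache$nbr
}
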