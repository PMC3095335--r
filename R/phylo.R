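# Distance computation, neighbor-joining with bootstrap, Newick I/O and a
# strict-clock age estimate.  Trees are ape "phylo" objects throughout.

#' p-distance matrix
#'
#' Proportion of differing compared positions between every pair of rows.
#' `nucleotide_transversion` counts only purine<->pyrimidine differences in
#' the numerator (the denominator stays all compared positions).  Pairwise
#' deletion drops positions gapped or ambiguous in either member of the pair;
#' complete deletion drops columns with a gap or ambiguity in any row.
#'
#' @param aln A `protein_alignment` or `codon_alignment`.  Nucleotide modes
#'   on a codon alignment operate on the flattened nucleotide columns;
#'   `protein` mode on a codon alignment translates first.
#' @param mode `"protein"`, `"nucleotide"` or `"nucleotide_transversion"`.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return Symmetric numeric matrix with zero diagonal; a pair with no
#'   comparable positions gets `NA`.
#' @export
p_distance <- function(aln,
                       mode = c("protein", "nucleotide", "nucleotide_transversion"),
                       deletion = c("pairwise", "complete")) {
  mode <- match.arg(mode)
  deletion <- match.arg(deletion)
  if (mode == "protein") {
    if (inherits(aln, "codon_alignment")) aln <- translate_alignment(aln)
    stopifnot(inherits(aln, "protein_alignment"))
    mat <- aln$mat
    missing <- mat == "-" | mat == "X"
  } else {
    if (inherits(aln, "codon_alignment")) {
      rows <- codon_rows(aln)
      mat <- do.call(rbind, strsplit(rows, ""))
      rownames(mat) <- aln$ids
    } else if (inherits(aln, "protein_alignment")) {
      stop("nucleotide modes need nucleotide data")
    } else if (is.character(aln) && !is.null(names(aln))) {
      if (length(unique(nchar(aln))) != 1L) stop("rows must have equal length")
      mat <- do.call(rbind, strsplit(toupper(aln), ""))
      rownames(mat) <- names(aln)
    } else stop("unsupported alignment input")
    missing <- mat == "-" | mat == "N"
  }
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 sequences")
  if (deletion == "complete") {
    keep <- colSums(missing) == 0L
    mat <- mat[, keep, drop = FALSE]
    missing <- missing[, keep, drop = FALSE]
  }
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !missing[i, ] & !missing[j, ]
      if (!any(ok)) {
        D[i, j] <- D[j, i] <- NA_real_
        next
      }
      a <- mat[i, ok]; b <- mat[j, ok]
      num <- if (mode == "nucleotide_transversion") sum(is_transversion(a, b))
             else sum(a != b)
      D[i, j] <- D[j, i] <- num / sum(ok)
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei NJ on a distance matrix; negative estimated branch
#' lengths are clamped to zero (with a message).
#'
#' @param D Symmetric distance matrix with labelled rows.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (anyNA(D)) {
    bad <- sort(which(is.na(D), arr.ind = TRUE)[1, ])
    stop("undefined distance between ", rownames(D)[bad[1]], " and ",
         colnames(D)[bad[2]])
  }
  tree <- ape::nj(stats::as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative NJ branch length(s) to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

resample_columns <- function(aln, idx) {
  if (inherits(aln, "codon_alignment")) {
    sub <- aln$codons[, idx, drop = FALSE]
    codon_alignment(setNames(apply(sub, 1, paste0, collapse = ""), aln$ids),
                    check_stops = FALSE)
  } else {
    sub <- aln$mat[, idx, drop = FALSE]
    protein_alignment(setNames(apply(sub, 1, paste0, collapse = ""), aln$ids))
  }
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns (codon columns for codon alignments) with
#' replacement, rebuilds the NJ tree for each replicate, and reports for each
#' internal edge of the point-estimate tree the percentage of replicates
#' containing that bipartition.  Deterministic given `seed`.
#'
#' @param aln A `protein_alignment` or `codon_alignment`.
#' @inheritParams p_distance
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A `phylo` tree with integer supports in `node.label`.
#' @export
bootstrap_support <- function(aln, mode = "protein", deletion = "pairwise",
                              n_reps = 1000L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  n_col <- if (inherits(aln, "codon_alignment")) ncol(aln$codons) else ncol(aln$mat)
  if (n_col < 2L) stop("alignment has fewer than 2 columns")
  point <- neighbor_joining(p_distance(aln, mode = mode, deletion = deletion))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n_col, n_col, replace = TRUE)
    boots[[r]] <- tryCatch({
      suppressMessages(neighbor_joining(
        p_distance(resample_columns(aln, idx), mode = mode, deletion = deletion)))
    }, error = function(e) NULL)
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- as.character(round(100 * counts / n_reps))
  point$node.label[1] <- ""  # root of the unrooted representation
  point
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Strict-clock divergence age
#'
#' Linear calibration: a split of known age `t_cal` spans distance `d_cal`,
#' so a pair at distance `d` diverged `t_cal * d / d_cal` time units ago.
#'
#' @param d_pair Distance between the pair of interest (>= 0).
#' @param d_cal Distance spanning the calibration split (> 0).
#' @param t_cal Age of the calibration split (e.g. Mya, > 0).
#' @return Age on the same scale as `t_cal`.
#' @export
strict_clock_age <- function(d_pair, d_cal, t_cal) {
  if (d_pair < 0 || d_cal <= 0 || t_cal <= 0) {
    stop("d_pair must be >= 0 and d_cal, t_cal > 0")
  }
  t_cal * d_pair / d_cal
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file; internal node labels are kept (they
#'   typically hold bootstrap supports).
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close) {
    stop("unbalanced parentheses in Newick (", open, " '(' vs ", close, " ')')")
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  tree
}

#' Write a Newick tree
#'
#' @param tree A `phylo` tree (supports in `node.label` are preserved).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
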