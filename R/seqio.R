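# Sequence containers and the protein-alignment -> codon-alignment stage.
#
# A protein_alignment stores one single-character matrix (rows = sequences,
# columns = alignment columns, gap "-").  A codon_alignment stores a matrix
# of 3-letter codon strings, column-synchronized with the protein alignment
# it was built from; a gap occupies a whole codon ("---").

PROTEIN_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")
NUC_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Read a FASTA file
#'
#' Reads protein or nucleotide FASTA, strips whitespace inside sequence
#' lines, upper-cases residues and (for nucleotide input) converts U to T.
#' Duplicate identifiers, empty files and characters outside the declared
#' alphabet are errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (alphabet == "nucleotide") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  allowed <- if (alphabet == "protein") PROTEIN_CHARS else NUC_CHARS
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[k])) stop("empty sequence for id ", ids[k])
    ch <- strsplit(seqs[k], "")[[1]]
    bad <- which(!(ch %in% allowed))
    if (length(bad)) {
      stop("illegal ", alphabet, " character '", ch[bad[1]], "' at position ",
           bad[1], " in sequence ", ids[k])
    }
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[k]), con)
    s <- seqs[[k]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a protein alignment
#'
#' @param seqs Named character vector of equal-length aligned protein
#'   sequences (gap `"-"`).
#' @return A `protein_alignment`: list with `ids` and the character matrix
#'   `mat` (rows = sequences).
#' @export
protein_alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("aligned rows must have equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  structure(list(ids = names(seqs), mat = mat), class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment:", length(x$ids), "sequences x", ncol(x$mat), "columns\n")
  invisible(x)
}

#' Construct a codon alignment from aligned CDS strings
#'
#' @param rows Named character vector of aligned coding sequences; length of
#'   every row must be a multiple of 3 and gaps must occupy whole codons.
#' @param check_stops Error on internal stop codons (default `TRUE`).
#' @return A `codon_alignment`: list with `ids` and matrix `codons` of
#'   3-letter codon strings.
#' @export
codon_alignment <- function(rows, check_stops = TRUE) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (anyDuplicated(names(rows))) stop("duplicate sequence ids")
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) stop("aligned rows must have equal length")
  if (lens[1] %% 3L != 0L) stop("row length ", lens[1], " is not a multiple of 3")
  n_col <- lens[1] %/% 3L
  codons <- matrix("", nrow = length(rows), ncol = n_col,
                   dimnames = list(names(rows), NULL))
  for (k in seq_along(rows)) {
    cs <- substring(rows[[k]], 3L * seq_len(n_col) - 2L, 3L * seq_len(n_col))
    part <- grepl("-", cs) & cs != "---"
    if (any(part)) {
      stop("gap does not occupy a whole codon in ", names(rows)[k],
           " at codon column ", which(part)[1])
    }
    if (check_stops) {
      aa <- translate_codon(cs[cs != "---" & !grepl("N", cs)])
      if (any(aa == "*", na.rm = TRUE)) {
        stop("internal stop codon in ", names(rows)[k], " at codon column ",
             which(cs %in% names(which(Biostrings::GENETIC_CODE == "*")))[1])
      }
    }
    codons[k, ] <- cs
  }
  structure(list(ids = names(rows), codons = codons), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$ids), "sequences x", ncol(x$codons),
      "codon columns\n")
  invisible(x)
}

#' Flatten a codon alignment back to nucleotide strings
#'
#' @param aln A `codon_alignment`.
#' @return Named character vector of aligned nucleotide rows.
#' @export
codon_rows <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  setNames(apply(aln$codons, 1, paste0, collapse = ""), aln$ids)
}

#' Back-translate a protein alignment with matching CDS sequences
#'
#' Builds the codon alignment column-synchronized with `protein_aln`: each
#' protein gap becomes `"---"` and each residue column becomes the next codon
#' of that sequence's CDS.  A terminal stop codon on a CDS is stripped
#' silently; internal stops and codons that do not translate to the aligned
#' residue are errors.
#'
#' @param protein_aln A [protein_alignment()].
#' @param cds Named character vector of unaligned CDS (same ids).
#' @return A [codon_alignment()].
#' @export
backtranslate <- function(protein_aln, cds) {
  stopifnot(inherits(protein_aln, "protein_alignment"))
  missing_ids <- setdiff(protein_aln$ids, names(cds))
  if (length(missing_ids)) {
    stop("no CDS for: ", paste(missing_ids, collapse = ", "))
  }
  n_col <- ncol(protein_aln$mat)
  out <- matrix("---", nrow = length(protein_aln$ids), ncol = n_col,
                dimnames = list(protein_aln$ids, NULL))
  stops <- names(which(Biostrings::GENETIC_CODE == "*"))
  for (id in protein_aln$ids) {
    s <- toupper(gsub("\\s", "", cds[[id]]))
    if (nchar(s) %% 3L != 0L) {
      stop("CDS length of ", id, " (", nchar(s), ") is not a multiple of 3")
    }
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    res_cols <- which(protein_aln$mat[id, ] != "-")
    # strip a genuine terminal stop (one codon beyond the aligned residues)
    if (length(cods) == length(res_cols) + 1L &&
        cods[length(cods)] %in% stops) {
      cods <- cods[-length(cods)]
    }
    if (length(cods) != length(res_cols)) {
      stop("length mismatch for ", id, ": ", length(res_cols),
           " aligned residues vs ", length(cods), " codons")
    }
    aa <- translate_codon(cods)
    exp_aa <- protein_aln$mat[id, res_cols]
    bad <- which(aa != exp_aa & exp_aa != "X" & !grepl("N", cods))
    if (length(bad)) {
      b <- bad[1]
      if (aa[b] == "*") {
        stop("internal stop codon ", cods[b], " in ", id,
             " at protein column ", res_cols[b])
      }
      stop("codon ", cods[b], " of ", id, " translates to ", aa[b],
           " but protein column ", res_cols[b], " has ", exp_aa[b])
    }
    out[id, res_cols] <- cods
  }
  codon_alignment(setNames(apply(out, 1, paste0, collapse = ""), protein_aln$ids),
                  check_stops = FALSE)
}

#' Translate a codon alignment back to a protein alignment
#'
#' @param aln A `codon_alignment`.
#' @return A `protein_alignment` (gap codons become `"-"`, codons containing
#'   N become `"X"`).
#' @export
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  mat <- aln$codons
  res <- matrix("-", nrow = nrow(mat), ncol = ncol(mat),
                dimnames = dimnames(mat))
  idx <- mat != "---"
  hasN <- grepl("N", mat)
  res[idx & !hasN] <- translate_codon(mat[idx & !hasN])
  res[idx & hasN] <- "X"
  protein_alignment(setNames(apply(res, 1, paste0, collapse = ""), aln$ids))
}

#' Remove gap-dominated codon columns
#'
#' Implements the keep/remove rule used when assembling the family codon
#' alignment: a codon column is removed when fewer than `min_present` rows
#' carry data (the default 3 removes columns where all sequences except one
#' or two are gaps); every other column is kept in order.
#'
#' @param aln A `codon_alignment`.
#' @param min_present Minimum number of non-gap rows for a column to be kept.
#' @return List with `alignment` (filtered `codon_alignment`), `removed`
#'   (1-based original codon-column indices that were dropped) and `kept_map`
#'   (for each retained column, its original index).
#' @export
filter_codon_columns <- function(aln, min_present = 3L) {
  stopifnot(inherits(aln, "codon_alignment"), min_present >= 1L)
  present <- colSums(aln$codons != "---")
  drop <- which(present < min_present)
  keep <- setdiff(seq_len(ncol(aln$codons)), drop)
  if (!length(keep)) stop("filtering removed every codon column")
  sub <- aln$codons[, keep, drop = FALSE]
  filtered <- codon_alignment(
    setNames(apply(sub, 1, paste0, collapse = ""), aln$ids),
    check_stops = FALSE)
  list(alignment = filtered, removed = drop, kept_map = keep)
}

#' Percent identity between two aligned rows
#'
#' Compares columns where neither row is a gap; for codon alignments whole
#' codons are compared.
#'
#' @param aln A `protein_alignment` or `codon_alignment`.
#' @param id_a,id_b Sequence identifiers.
#' @return Percentage in \[0, 100\], or `NA` when no comparable columns exist.
#' @export
pairwise_identity <- function(aln, id_a, id_b) {
  mat <- if (inherits(aln, "codon_alignment")) aln$codons
         else if (inherits(aln, "protein_alignment")) aln$mat
         else stop("aln must be a protein_alignment or codon_alignment")
  gap <- if (inherits(aln, "codon_alignment")) "---" else "-"
  for (id in c(id_a, id_b)) {
    if (!id %in% rownames(mat)) stop("unknown sequence id: ", id)
  }
  a <- mat[id_a, ]; b <- mat[id_b, ]
  ok <- a != gap & b != gap
  if (!any(ok)) return(NA_real_)
  100 * sum(a[ok] == b[ok]) / sum(ok)
}

#' Read a cluster assignment table
#'
#' Two-column TSV (sequence id, cluster label); lines starting with `#` are
#' comments.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sequence id to cluster label.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) != 2L) stop("group table must have exactly 2 tab-separated columns")
  if (anyDuplicated(tab[[1]])) {
    stop("duplicate id in group table: ", tab[[1]][duplicated(tab[[1]])][1])
  }
  setNames(tab[[2]], tab[[1]])
}
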