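# Shared fixture builders.  Everything is generated in code; nothing is read
# from disk except through tempfiles written here.

toy_protein_aln <- function() {
  protein_alignment(c(
    seq1 = "MKV-LD",
    seq2 = "MQVELD",
    seq3 = "MQV-LD",
    seq4 = "MKVELE"
  ))
}

toy_cds <- function() {
  c(seq1 = "ATGAAAGTTCTTGAT",
    seq2 = "ATGCAAGTGGAACTGGAC",
    seq3 = "ATGCAGGTTTTAGAT",
    seq4 = "ATGAAGGTCGAGCTTGAATAA")   # carries a terminal stop
}

# unrooted 6-taxon tree used for simulation-scale fits
tree6 <- function(bl = 0.2, bl_int = 0.1) {
  ape::read.tree(text = sprintf(
    "((t1:%f,t2:%f):%f,(t3:%f,t4:%f):%f,(t5:%f,t6:%f):%f);",
    bl, bl, bl_int, bl, bl, bl_int, bl, bl, bl_int))
}

# two cherries: clusters {a1,a2} and {b1,b2}
tree_cherries <- function() {
  ape::read.tree(text = "((a1:0.1,a2:0.1):0.2,(b1:0.1,b2:0.1):0.2);")
}

write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  path
}

# columns of a protein_alignment as strings, for hand-built expectations
aln_column <- function(aln, j) paste(aln$mat[, j], collapse = "")

# Hand-built Type-II scenario over the cherries tree, clusters {a1,a2} and
# {b1,b2}, charge partition (K/R/H positive, D/E negative, rest neutral).
# Columns:
#   1-5:  a = K..K, b = D..D  -> applicable, differing, radical (+ vs -)
#   6:    a = {K,D} event (radical), b monomorphic   -> not applicable
#   7:    a mono, b = {V,A} event (conserved)        -> not applicable
#   8:    a = {S,T} event (conserved), b mono        -> not applicable
#   9:    a mono, b = {I,L} event (conserved)        -> not applicable
#   10:   a = {F,Y} event (conserved), b mono        -> not applicable
# so p_r0 = 1/5 and pi_R = 1.
type2_fixture <- function() {
  protein_alignment(c(
    a1 = "KKKKKKASLF",
    a2 = "KKKKKDATLY",
    b1 = "DDDDDAVFIF",
    b2 = "DDDDDAAFLF"
  ))
}
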