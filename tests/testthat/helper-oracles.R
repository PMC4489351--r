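# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force Dollo minimum: the smallest number of tree edges whose united
# leaf clades cover every lost leaf and no functional leaf (unknown leaves are
# free). Enumerates all 2^n_edge edge subsets with a doubling bitmask DP over
# leaf sets.
dollo_oracle_setup <- function(tree) {
  ntip <- length(tree$tip.label)
  clade_mask <- vapply(seq_len(nrow(tree$edge)), function(i) {
    node <- tree$edge[i, 2L]
    tips <- if (node <= ntip) node else
      match(ape::extract.clade(tree, node)$tip.label, tree$tip.label)
    as.integer(sum(bitwShiftL(1L, tips - 1L)))
  }, integer(1))
  un <- 0L
  sz <- 0L
  for (m in clade_mask) {
    un <- c(un, bitwOr(un, m))
    sz <- c(sz, sz + 1L)
  }
  list(un = un, sz = sz, ntip = ntip)
}

dollo_oracle_min <- function(setup, lost_idx) {
  lost_mask <- as.integer(sum(bitwShiftL(1L, lost_idx - 1L)))
  func_mask <- as.integer(sum(bitwShiftL(1L, setdiff(seq_len(setup$ntip), lost_idx) - 1L)))
  feasible <- bitwAnd(setup$un, func_mask) == 0L &
    bitwAnd(lost_mask, bitwNot(setup$un)) == 0L
  min(setup$sz[feasible])
}

# Stop-codon oracle: ungap the row across the coding region (frame anchored
# at the ATG1 column, so indels shift the frame cumulatively) and translate
# with Biostrings; premature stops are the '*' positions.
oracle_stop_codons <- function(aln, species) {
  ann <- aln$annotation
  row <- strsplit(aln$seqs[[species]], "")[[1]]
  cols <- ann$coding_block[1]:(ann$donor_pos - 1)
  seq <- paste(row[cols][row[cols] != "-"], collapse = "")
  seq <- substr(seq, 1, 3 * (nchar(seq) %/% 3))
  if (nchar(seq) == 0) return(integer(0))
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                             if.fuzzy.codon = "X"))
  which(strsplit(prot, "")[[1]] == "*")
}

# codon index (in the ATG1-anchored frame of the row) of each premature_stop
# lesion reported by the package
reported_stop_codons <- function(aln, species) {
  ann <- aln$annotation
  row <- strsplit(aln$seqs[[species]], "")[[1]]
  les <- detect_orf_disruptions(aln, species)
  les <- les[les$type == "premature_stop", , drop = FALSE]
  if (!nrow(les)) return(integer(0))
  cols <- ann$coding_block[1]:(ann$donor_pos - 1)
  base_cols <- cols[row[cols] != "-"]
  sort(vapply(les$start, function(s) {
    (match(s, base_cols) - 1L) %/% 3L + 1L
  }, integer(1)))
}

# a template alignment with one extra row carrying targeted edits, expressed
# as a list of (col, base) substitutions and (col, len) deletions
mutated_alignment <- function(subs = NULL, dels = NULL, species = "mut") {
  tpl <- region_template()
  row <- strsplit(tpl$sequence, "")[[1]]
  if (!is.null(subs)) for (s in subs) row[s[[1]]] <- s[[2]]
  if (!is.null(dels)) for (d in dels) row[d[1]:(d[1] + d[2] - 1)] <- "-"
  seqs <- c(Reference = tpl$sequence, paste(row, collapse = ""))
  names(seqs)[2] <- species
  region_alignment(seqs, tpl$annotation)
}
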