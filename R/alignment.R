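#' Aligned orthologous first-exon regions
#'
#' Bundles a set of aligned, gapped nucleotide rows (one per species, the
#' reference species first) with the [feature_annotation()] giving the
#' reference coordinates of the functional blocks, and an optional per-species
#' coverage flag marking assembly gaps / low-coverage rows whose verdict must
#' be reported as unknown downstream.
#'
#' Rows are plain upper-case character strings over `A`, `C`, `G`, `T`, `N`
#' and the gap character `-`; all rows must have equal length and the
#' reference row may not contain `N` inside annotated blocks.
#'
#' @param seqs named character vector of aligned rows; the first element is
#'   the reference.
#' @param annotation a [feature_annotation()].
#' @param coverage_flag logical vector (recycled or named) marking rows with
#'   doubtful assembly coverage. Default all `FALSE`.
#' @return An object of class `region_alignment`.
#' @export
region_alignment <- function(seqs, annotation, coverage_flag = FALSE) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all rows must be named by species")
  if (anyDuplicated(names(seqs)))
    stop("duplicate species names in alignment")
  nm <- names(seqs)
  seqs <- stats::setNames(toupper(as.character(seqs)), nm)
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("all alignment rows must have equal length")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("alignment rows may only contain A,C,G,T,N,-: ", names(seqs)[bad][1])
  stopifnot(inherits(annotation, "feature_annotation"))
  if (annotation$donor_pos + 1L > w)
    stop("annotation exceeds alignment width")

  if (length(coverage_flag) == 1L && is.null(names(coverage_flag)))
    coverage_flag <- stats::setNames(rep(coverage_flag, length(seqs)), names(seqs))
  if (!is.null(names(coverage_flag))) {
    cf <- stats::setNames(rep(FALSE, length(seqs)), names(seqs))
    cf[intersect(names(coverage_flag), names(seqs))] <-
      coverage_flag[intersect(names(coverage_flag), names(seqs))]
    coverage_flag <- cf
  } else {
    stopifnot(length(coverage_flag) == length(seqs))
    coverage_flag <- stats::setNames(as.logical(coverage_flag), names(seqs))
  }

  ref <- .aln_chars(seqs[[1L]])
  blocks <- c(
    annotation$promoter_block[1L]:annotation$promoter_block[2L],
    annotation$tss_block[1L]:annotation$tss_block[2L],
    annotation$coding_block[1L]:annotation$coding_block[2L]
  )
  if (any(ref[blocks] == "N"))
    stop("reference row contains N within annotated blocks")

  structure(
    list(seqs = seqs, annotation = annotation, coverage_flag = coverage_flag),
    class = "region_alignment"
  )
}

#' @export
print.region_alignment <- function(x, ...) {
  cat(sprintf(
    "Region alignment: %d species x %d columns (reference: %s)\n",
    length(x$seqs), nchar(x$seqs[[1L]]), names(x$seqs)[1L]
  ))
  if (any(x$coverage_flag))
    cat("  coverage-flagged:", paste(names(x$coverage_flag)[x$coverage_flag], collapse = ", "), "\n")
  print(x$annotation)
  invisible(x)
}

#' @export
names.region_alignment <- function(x) names(x$seqs)

# split an aligned row into a character vector of columns
.aln_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# the first n columns at or after column `from` where the reference has a base
.ref_base_cols <- function(ref_chars, from, n) {
  cols <- which(ref_chars != "-")
  cols <- cols[cols >= from]
  if (length(cols) < n) return(integer(0))
  cols[seq_len(n)]
}

#' Read / write a region alignment
#'
#' The alignment travels as aligned FASTA (gap character `-`, reference row
#' first) plus a YAML annotation config; see [read_feature_annotation()].
#'
#' @param fasta path to an aligned FASTA file.
#' @param annotation path to the YAML annotation, or a `feature_annotation`.
#' @param coverage_flag as in [region_alignment()].
#' @return `read_region_alignment()` returns a `region_alignment`.
#' @export
read_region_alignment <- function(fasta, annotation, coverage_flag = FALSE) {
  ss <- Biostrings::readBStringSet(fasta)
  seqs <- stats::setNames(as.character(ss), names(ss))
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- read_feature_annotation(annotation)
  region_alignment(seqs, annotation, coverage_flag)
}

#' @rdname read_region_alignment
#' @param aln a `region_alignment`.
#' @export
write_region_alignment <- function(aln, fasta, annotation = NULL) {
  stopifnot(inherits(aln, "region_alignment"))
  ss <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(annotation)) write_feature_annotation(aln$annotation, annotation)
  invisible(fasta)
}
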