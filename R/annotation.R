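#' Feature annotation of an alternative first-exon region
#'
#' Describes, in alignment columns (1-based, inclusive), where the functional
#' blocks of the exon-1A-like region sit on the reference row of an alignment:
#' the upstream promoter block, the conserved block containing the mapped
#' transcriptional start site (TSS), the two in-frame start codons, the coding
#' portion of the exon, and the first intronic base where the splice-donor
#' dinucleotide (GT) begins.
#'
#' @param promoter_block integer(2). Columns of the putative promoter block
#'   (roughly 500 bp upstream of ATG1), strictly upstream of `tss_block`.
#' @param tss_block integer(2). Columns of the conserved block where the
#'   transcriptional start site is mapped in the reference species.
#' @param atg1_pos,atg2_pos integer(1). Column of the A of each annotated
#'   start codon; ATG1 upstream of ATG2, both in the same reading frame.
#' @param coding_block integer(2). Columns of the coding portion of the exon;
#'   starts at `atg1_pos`, ends at or before `donor_pos`.
#' @param donor_pos integer(1). Column of the first intronic base; the donor
#'   dinucleotide occupies this column and the next reference base.
#' @param width optional integer(1), total alignment width, used for bounds
#'   checking when known.
#'
#' @return An object of class `feature_annotation`.
#' @export
#' @examples
#' feature_annotation(
#'   promoter_block = c(1, 440), tss_block = c(441, 520),
#'   atg1_pos = 561, atg2_pos = 591,
#'   coding_block = c(561, 650), donor_pos = 651
#' )
feature_annotation <- function(promoter_block, tss_block, atg1_pos, atg2_pos,
                               coding_block, donor_pos, width = NULL) {
  as_iv <- function(x, nm) {
    x <- as.integer(x)
    if (length(x) != 2L || any(is.na(x)) || x[1L] > x[2L])
      stop(sprintf("'%s' must be an increasing integer interval of length 2", nm))
    x
  }
  promoter_block <- as_iv(promoter_block, "promoter_block")
  tss_block <- as_iv(tss_block, "tss_block")
  coding_block <- as_iv(coding_block, "coding_block")
  atg1_pos <- as.integer(atg1_pos)
  atg2_pos <- as.integer(atg2_pos)
  donor_pos <- as.integer(donor_pos)

  if (promoter_block[2L] >= tss_block[1L])
    stop("promoter_block must lie strictly upstream of tss_block")
  if (tss_block[2L] > atg1_pos)
    stop("tss_block must end at or before atg1_pos")
  if (atg1_pos >= atg2_pos)
    stop("atg1_pos must be upstream of atg2_pos")
  if (atg2_pos + 2L > coding_block[2L])
    stop("atg2_pos must lie within coding_block")
  if (coding_block[1L] != atg1_pos)
    stop("coding_block must start at atg1_pos")
  if (coding_block[2L] >= donor_pos + 1L && coding_block[2L] > donor_pos)
    stop("coding_block must end at or before donor_pos")
  if (!is.null(width) && donor_pos + 1L > width)
    stop("annotation exceeds alignment width")

  structure(
    list(
      promoter_block = promoter_block,
      tss_block = tss_block,
      atg1_pos = atg1_pos,
      atg2_pos = atg2_pos,
      coding_block = coding_block,
      donor_pos = donor_pos
    ),
    class = "feature_annotation"
  )
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat("Feature annotation (alignment columns, 1-based inclusive)\n")
  cat(sprintf("  promoter block : %d-%d\n", x$promoter_block[1], x$promoter_block[2]))
  cat(sprintf("  TSS block      : %d-%d\n", x$tss_block[1], x$tss_block[2]))
  cat(sprintf("  ATG1 / ATG2    : %d / %d\n", x$atg1_pos, x$atg2_pos))
  cat(sprintf("  coding block   : %d-%d\n", x$coding_block[1], x$coding_block[2]))
  cat(sprintf("  splice donor   : %d\n", x$donor_pos))
  invisible(x)
}

#' Read or write a feature annotation as a YAML config
#'
#' The on-disk format is a flat YAML mapping with 1-based inclusive
#' coordinates, e.g. `promoter_block: [1, 440]`, `atg1_pos: 561`.
#'
#' @param path file path.
#' @return `read_feature_annotation()` returns a `feature_annotation`;
#'   `write_feature_annotation()` returns `path` invisibly.
#' @export
read_feature_annotation <- function(path) {
  y <- yaml::read_yaml(path)
  feature_annotation(
    promoter_block = y$promoter_block, tss_block = y$tss_block,
    atg1_pos = y$atg1_pos, atg2_pos = y$atg2_pos,
    coding_block = y$coding_block, donor_pos = y$donor_pos
  )
}

#' @rdname read_feature_annotation
#' @param ann a `feature_annotation`.
#' @export
write_feature_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "feature_annotation"))
  yaml::write_yaml(
    list(
      promoter_block = as.integer(ann$promoter_block),
      tss_block = as.integer(ann$tss_block),
      atg1_pos = ann$atg1_pos, atg2_pos = ann$atg2_pos,
      coding_block = as.integer(ann$coding_block), donor_pos = ann$donor_pos
    ),
    path
  )
  invisible(path)
}
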