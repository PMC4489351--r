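#' Exon model for isoform quantification
#'
#' Holds the lengths (bp) of the two alternative first exons and of the
#' shared downstream control exon used to normalise read counts. The
#' defaults are the human EDARADD-like exon sizes: 228 bp (exon 1A), 245 bp
#' (exon 1B), 426 bp (exon 6).
#'
#' @param exon_1A,exon_1B,exon_6 exon lengths in bp (all >= 1).
#' @return An object of class `exon_model`.
#' @export
exon_model <- function(exon_1A = 228L, exon_1B = 245L, exon_6 = 426L) {
  lens <- c(exon_1A = as.numeric(exon_1A), exon_1B = as.numeric(exon_1B),
            exon_6 = as.numeric(exon_6))
  if (any(is.na(lens)) || any(lens < 1))
    stop("all exon lengths must be >= 1")
  structure(as.list(lens), class = "exon_model")
}

.check_counts <- function(counts) {
  needed <- c("exon_1A", "exon_1B", "exon_6")
  if (!all(needed %in% names(counts)))
    stop("counts must have components exon_1A, exon_1B, exon_6")
  x <- vapply(needed, function(k) as.numeric(counts[[k]]), numeric(1))
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("read counts must be nonnegative integers")
  x
}

#' Normalise read counts by exon size
#'
#' The number of reads falling in an exon scales with its length, so counts
#' are converted to per-bp read densities before any comparison.
#'
#' @param counts a named list/vector with `exon_1A`, `exon_1B`, `exon_6`
#'   read counts (nonnegative integers).
#' @param model an [exon_model()].
#' @return Named numeric vector of per-bp densities.
#' @export
#' @examples
#' normalize_counts(c(exon_1A = 228, exon_1B = 245, exon_6 = 426), exon_model())
normalize_counts <- function(counts, model = exon_model()) {
  stopifnot(inherits(model, "exon_model"))
  x <- .check_counts(counts)
  c(exon_1A = x[["exon_1A"]] / model$exon_1A,
    exon_1B = x[["exon_1B"]] / model$exon_1B,
    exon_6 = x[["exon_6"]] / model$exon_6)
}

#' Check that first-exon reads are coherent with the control exon
#'
#' Every transcript carries exactly one of the two first exons and the
#' control exon, so under even per-transcript coverage the mean of the two
#' first-exon read densities matches the control-exon density. The relative
#' deviation `|d_1A + d_1B - 2 d_6| / (2 d_6)` is compared to `tol`.
#'
#' @inheritParams normalize_counts
#' @param tol relative tolerance (default 0.2).
#' @return A list with `pass` (logical; `NA` when the control exon has zero
#'   reads) and `deviation`.
#' @export
consistency_check <- function(counts, model = exon_model(), tol = 0.2) {
  d <- normalize_counts(counts, model)
  if (d[["exon_6"]] == 0)
    return(list(pass = NA, deviation = NA_real_))
  dev <- abs(d[["exon_1A"]] + d[["exon_1B"]] - 2 * d[["exon_6"]]) / (2 * d[["exon_6"]])
  list(pass = dev <= tol, deviation = unname(dev))
}

#' Chi-squared test of equal molar expression of the two first exons
#'
#' Under the null that both isoforms are present at the same molar level,
#' the expected read counts are proportional to exon length:
#' `E_1A = N L_1A / (L_1A + L_1B)` with `N = reads_1A + reads_1B`. The
#' Pearson chi-squared statistic over the two cells has 1 degree of freedom.
#'
#' @param reads_1A,reads_1B observed read counts (their sum must be >= 1).
#' @param model an [exon_model()].
#' @return A list with `chi2_stat` and `p_raw`.
#' @export
#' @examples
#' test_equal_expression(228, 245) # perfectly length-proportional: chi2 = 0
test_equal_expression <- function(reads_1A, reads_1B, model = exon_model()) {
  stopifnot(inherits(model, "exon_model"))
  n <- reads_1A + reads_1B
  if (n < 1) stop("reads_1A + reads_1B must be >= 1")
  p <- c(model$exon_1A, model$exon_1B)
  p <- p / sum(p)
  ht <- suppressWarnings(
    stats::chisq.test(c(reads_1A, reads_1B), p = p, correct = FALSE)
  )
  list(chi2_stat = unname(ht$statistic), p_raw = unname(ht$p.value))
}

#' Classify the isoform balance of one library
#'
#' Applies, in order: the detection floor (`B_only` when the exon-1A density
#' falls below `floor` times the control-exon density, `A_only`
#' symmetrically), then the length-proportional chi-squared test with
#' Bonferroni correction over `m_tests` libraries. Libraries whose adjusted
#' p-value is not significant are `A=B`; significant libraries are `B>A` or
#' `A>B` by the sign of the density difference.
#'
#' @inheritParams normalize_counts
#' @param alpha family-wise significance level (default 0.05).
#' @param m_tests number of tests for the Bonferroni correction (default 7,
#'   one per library in the reference cell-line panel).
#' @param floor detection floor as a fraction of the control-exon density
#'   (default 0.05).
#' @param library_id optional library label.
#' @return A one-row data frame: `library_id`, `category` (one of `A=B`,
#'   `B>A`, `A>B`, `B_only`, `A_only`, or `NA` for an all-zero library),
#'   `chi2_stat`, `p_raw`, `p_adj`, `fold_change_B_over_A` (per-bp density
#'   ratio), `consistency_deviation`.
#' @export
classify_library <- function(counts, model = exon_model(), alpha = 0.05,
                             m_tests = 7L, floor = 0.05,
                             library_id = NA_character_) {
  d <- normalize_counts(counts, model)
  dev <- consistency_check(counts, model)$deviation
  row <- function(category, chi2 = NA_real_, p_raw = NA_real_, p_adj = NA_real_) {
    fold <- if (d[["exon_1A"]] > 0) d[["exon_1B"]] / d[["exon_1A"]] else Inf
    data.frame(
      library_id = library_id, category = category,
      chi2_stat = chi2, p_raw = p_raw, p_adj = p_adj,
      fold_change_B_over_A = fold, consistency_deviation = dev,
      stringsAsFactors = FALSE
    )
  }
  if (sum(d) == 0)
    return(row(NA_character_))
  if (d[["exon_1A"]] < floor * d[["exon_6"]])
    return(row("B_only"))
  if (d[["exon_1B"]] < floor * d[["exon_6"]])
    return(row("A_only"))
  ht <- test_equal_expression(counts[["exon_1A"]], counts[["exon_1B"]], model)
  p_adj <- min(1, m_tests * ht$p_raw)
  category <- if (p_adj >= alpha) "A=B"
    else if (d[["exon_1B"]] > d[["exon_1A"]]) "B>A" else "A>B"
  row(category, ht$chi2_stat, ht$p_raw, p_adj)
}

#' Classify every library of a count table
#'
#' @param counts a data frame with columns `library` (or `library_id`),
#'   `exon_1A`, `exon_1B`, `exon_6`.
#' @inheritParams classify_library
#' @return A data frame with one [classify_library()] row per library.
#' @export
classify_libraries <- function(counts, model = exon_model(), alpha = 0.05,
                               m_tests = nrow(counts), floor = 0.05) {
  id_col <- intersect(c("library", "library_id"), names(counts))[1L]
  if (is.na(id_col)) stop("counts must have a 'library' column")
  if (anyDuplicated(counts[[id_col]])) stop("duplicate library names")
  out <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    classify_library(counts[i, ], model, alpha, m_tests, floor,
                     library_id = as.character(counts[[id_col]][i]))
  }))
  rownames(out) <- NULL
  out
}
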