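#' Classify a Kozak context
#'
#' Classifies the sequence context of a start codon by the two positions with
#' the dominant effect on initiation efficiency in the vertebrate consensus:
#' a purine (A/G) at -3 and a G at +4 (numbering the A of the ATG as +1).
#' `strong` means both hold, `adequate` exactly one, `weak` neither.
#'
#' @param context character string holding the window around the ATG; by
#'   default a 10-mer covering -6..+4 with the ATG at positions 7-9. For
#'   windows truncated by a sequence edge, pass the available characters and
#'   give `atg_at`, the position of the A within `context`; positions missing
#'   from the window simply cannot satisfy their rule.
#' @param atg_at position of the A of the ATG within `context`. Defaults to
#'   `nchar(context) - 3` (i.e. ATG followed by a single +4 base).
#' @return `"strong"`, `"adequate"` or `"weak"`; `NA` if a scored position is
#'   an ambiguous base (`N`).
#' @export
#' @examples
#' score_kozak("GCCACCATGG") # strong
#' score_kozak("GCCTCCATGC") # weak
score_kozak <- function(context, atg_at = nchar(context) - 3L) {
  context <- toupper(context)
  n <- nchar(context)
  if (atg_at < 1L || atg_at + 2L > n)
    stop("'atg_at' does not fit an ATG inside 'context'")
  if (substr(context, atg_at, atg_at + 2L) != "ATG")
    stop("no intact ATG at 'atg_at'; Kozak class is defined only for intact ATGs")
  minus3 <- if (atg_at - 3L >= 1L) substr(context, atg_at - 3L, atg_at - 3L) else ""
  plus4 <- if (atg_at + 3L <= n) substr(context, atg_at + 3L, atg_at + 3L) else ""
  if (minus3 == "N" || plus4 == "N") return(NA_character_)
  hits <- (minus3 %in% c("A", "G")) + (plus4 == "G")
  c("weak", "adequate", "strong")[hits + 1L]
}

# indel runs of a row against the reference between alignment columns
# from..to (inclusive). Columns where BOTH the row and the reference are
# gapped are uninformative and do not break a run. Returns a data frame with
# kind ("deletion"/"insertion"), start/end alignment columns and the ungapped
# length of the affected segment.
.indel_runs <- function(row_chars, ref_chars, from, to) {
  cols <- from:to
  ref <- ref_chars[cols]
  row <- row_chars[cols]
  keep <- !(ref == "-" & row == "-")
  cols <- cols[keep]
  state <- ifelse(ref[keep] != "-" & row[keep] == "-", "deletion",
           ifelse(ref[keep] == "-" & row[keep] != "-", "insertion", "match"))
  if (!length(state)) {
    return(data.frame(kind = character(0), start = integer(0), end = integer(0),
                      length_bp = integer(0)))
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values != "match")
  data.frame(
    kind = r$values[idx],
    start = cols[starts[idx]],
    end = cols[ends[idx]],
    length_bp = r$lengths[idx],
    stringsAsFactors = FALSE
  )
}

.empty_lesions <- function() {
  data.frame(type = character(0), start = integer(0), end = integer(0),
             length_bp = integer(0), detail = character(0),
             stringsAsFactors = FALSE)
}

.lesion <- function(type, start, end, length_bp, detail = "") {
  data.frame(type = type, start = as.integer(start), end = as.integer(end),
             length_bp = as.integer(length_bp), detail = detail,
             stringsAsFactors = FALSE)
}

# resolve a row of a region_alignment by name or string
.resolve_row <- function(aln, row) {
  stopifnot(inherits(aln, "region_alignment"))
  if (length(row) != 1L) stop("'row' must name a single species")
  if (!row %in% names(aln$seqs)) stop("unknown species: ", row)
  list(
    row = .aln_chars(aln$seqs[[row]]),
    ref = .aln_chars(aln$seqs[[1L]]),
    ann = aln$annotation,
    coverage = isTRUE(aln$coverage_flag[[row]])
  )
}

#' Read the status of the two annotated start codons in one species
#'
#' Reads the 3 bases of each annotated start codon in a species row (at the
#' alignment columns where the reference carries the codon), decides whether
#' the codon is an intact ATG, and scores the Kozak context of intact codons
#' from the row's own ungapped sequence. A codon overlapping an alignment gap
#' in this row is reported with `-` characters and is not intact; a codon
#' containing `N` has unknown (`NA`) status.
#'
#' @param aln a [region_alignment()].
#' @param row species name of the row to scan.
#' @return A list of two start-codon status lists, each with elements `which`
#'   (1 or 2), `observed_codon`, `intact` (logical, `NA` for ambiguous) and
#'   `kozak_class` (defined only when intact).
#' @export
scan_start_codons <- function(aln, row) {
  x <- .resolve_row(aln, row)
  lapply(c(1L, 2L), function(which) {
    pos <- if (which == 1L) x$ann$atg1_pos else x$ann$atg2_pos
    cols <- .ref_base_cols(x$ref, pos, 3L)
    codon <- paste(x$row[cols], collapse = "")
    intact <- if (grepl("N", codon)) NA else codon == "ATG"
    kz <- NA_character_
    if (isTRUE(intact)) {
      # Kozak window in the row's own ungapped coordinates
      ungapped_cols <- which(x$row != "-")
      i <- match(cols[1L], ungapped_cols)
      lo <- max(1L, i - 6L)
      hi <- min(length(ungapped_cols), i + 5L)
      window <- paste(x$row[ungapped_cols[lo:hi]], collapse = "")
      kz <- score_kozak(window, atg_at = i - lo + 1L)
    }
    list(which = which, observed_codon = codon, intact = intact, kozak_class = kz)
  })
}

#' Detect ORF-disrupting lesions in the coding block of one species
#'
#' Reports every maximal indel (a run of gap columns in the row against the
#' reference, or an insertion where the reference is gapped) inside the coding
#' block whose ungapped length is not a multiple of 3 as a `frameshift_indel`,
#' and every in-frame stop codon (TAA/TAG/TGA) strictly upstream of the splice
#' donor as a `premature_stop`. The reading frame is anchored at the annotated
#' ATG1 column even when ATG1 itself is mutated, and is shifted cumulatively
#' by upstream indels (translation simply walks the row's ungapped bases from
#' the ATG1 column).
#'
#' @inheritParams scan_start_codons
#' @return A lesion data frame (columns `type`, `start`, `end`, `length_bp`,
#'   `detail`); a single `region_absent` lesion if the coding block is
#'   entirely gapped in this row.
#' @export
detect_orf_disruptions <- function(aln, row) {
  x <- .resolve_row(aln, row)
  cb <- x$ann$coding_block
  ref_cols <- which(x$ref != "-")
  ref_cols <- ref_cols[ref_cols >= cb[1L] & ref_cols <= cb[2L]]
  if (all(x$row[ref_cols] == "-")) {
    return(.lesion("region_absent", cb[1L], cb[2L],
                   length(ref_cols), "coding block entirely gapped"))
  }

  runs <- .indel_runs(x$row, x$ref, cb[1L], cb[2L])
  fs <- runs[runs$length_bp %% 3L != 0L, , drop = FALSE]
  lesions <- .empty_lesions()
  if (nrow(fs)) {
    lesions <- do.call(rbind, lapply(seq_len(nrow(fs)), function(i) {
      .lesion("frameshift_indel", fs$start[i], fs$end[i], fs$length_bp[i],
              paste0(fs$kind[i], " of ", fs$length_bp[i], " bp"))
    }))
  }

  # translate the row from the ATG1 column to the donor, gaps dropped
  tr_cols <- cb[1L]:(x$ann$donor_pos - 1L)
  tr_cols <- tr_cols[x$row[tr_cols] != "-"]
  n_codon <- length(tr_cols) %/% 3L
  if (n_codon > 0L) {
    for (k in seq_len(n_codon)) {
      cc <- tr_cols[(3L * k - 2L):(3L * k)]
      codon <- paste(x$row[cc], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA")) {
        lesions <- rbind(lesions, .lesion(
          "premature_stop", cc[1L], cc[3L], 3L,
          paste0(codon, " at codon ", k, " from the ATG1 frame anchor")
        ))
      }
    }
  }
  lesions[order(lesions$start), , drop = FALSE]
}

#' Check the splice-donor dinucleotide of one species
#'
#' The donor is intact only if the two bases at the annotated donor columns
#' are exactly `GT` (canonical donor; any other dinucleotide, including GC,
#' is treated as donor loss).
#'
#' @inheritParams scan_start_codons
#' @return A list with `intact` (logical, `NA` if the donor contains `N`),
#'   `observed` (the dinucleotide as read, `-` for gapped columns) and
#'   `lesions` (a `donor_loss` lesion when not intact).
#' @export
check_splice_donor <- function(aln, row) {
  x <- .resolve_row(aln, row)
  cols <- .ref_base_cols(x$ref, x$ann$donor_pos, 2L)
  obs <- paste(x$row[cols], collapse = "")
  if (grepl("N", obs)) {
    return(list(intact = NA, observed = obs, lesions = .empty_lesions()))
  }
  if (obs == "GT") {
    return(list(intact = TRUE, observed = obs, lesions = .empty_lesions()))
  }
  detail <- if (grepl("-", obs)) "donor deleted" else paste0("donor is ", obs)
  list(intact = FALSE, observed = obs,
       lesions = .lesion("donor_loss", cols[1L], cols[length(cols)], 2L, detail))
}

#' Assess the promoter block of one species
#'
#' The promoter is `absent` when at least `absent_frac` of the reference bases
#' of the promoter block are gapped in the row; `rearranged` when a deletion
#' of at least `indel_min_bp` overlaps the TSS block or an insertion of at
#' least `indel_min_bp` lies within the TSS block; otherwise `intact`. All
#' indels of at least `indel_min_bp` across the promoter + TSS region are
#' emitted as lesions.
#'
#' @inheritParams scan_start_codons
#' @param indel_min_bp minimum indel length (bp) counted as a promoter
#'   rearrangement; default 30, well below the archetypal 72-bp insertion and
#'   above alignment noise.
#' @param absent_frac gap fraction of the promoter block above which the
#'   promoter is called absent; default 0.9.
#' @return A list with `status` (`"intact"`, `"rearranged"` or `"absent"`)
#'   and `lesions`.
#' @export
assess_promoter <- function(aln, row, indel_min_bp = 30L, absent_frac = 0.9) {
  x <- .resolve_row(aln, row)
  pb <- x$ann$promoter_block
  tb <- x$ann$tss_block

  prom_cols <- which(x$ref != "-")
  prom_cols <- prom_cols[prom_cols >= pb[1L] & prom_cols <= pb[2L]]
  gap_frac <- mean(x$row[prom_cols] == "-")

  runs <- .indel_runs(x$row, x$ref, pb[1L], tb[2L])
  big <- runs[runs$length_bp >= indel_min_bp, , drop = FALSE]
  lesions <- .empty_lesions()
  rearranged <- FALSE
  if (nrow(big)) {
    for (i in seq_len(nrow(big))) {
      type <- if (big$kind[i] == "deletion") "promoter_deletion" else "promoter_insertion"
      overlaps_tss <- big$start[i] <= tb[2L] && big$end[i] >= tb[1L]
      within_tss <- big$start[i] >= tb[1L] && big$end[i] <= tb[2L]
      if ((type == "promoter_deletion" && overlaps_tss) ||
          (type == "promoter_insertion" && within_tss))
        rearranged <- TRUE
      lesions <- rbind(lesions, .lesion(
        type, big$start[i], big$end[i], big$length_bp[i],
        paste0(big$kind[i], " of ", big$length_bp[i], " bp",
               if (overlaps_tss) ", overlapping the TSS block" else "")
      ))
    }
  }

  status <- if (gap_frac >= absent_frac) "absent" else if (rearranged) "rearranged" else "intact"
  if (status == "absent" && !nrow(lesions)) {
    lesions <- .lesion("promoter_deletion", pb[1L], pb[2L],
                       sum(x$row[prom_cols] == "-"), "promoter block gapped")
  }
  list(status = status, lesions = lesions)
}

#' Build the full lesion report of one species
#'
#' Deterministic union of the four feature detectors: promoter assessment,
#' splice-donor check, start-codon scan (with Kozak scoring) and
#' ORF-disruption detection. A row whose whole annotated region is gapped
#' yields a single `region_absent` lesion. Non-intact start codons contribute
#' `start1_loss` / `start2_loss` lesions. The species' coverage flag is
#' propagated so that low-coverage rows are reported as unknown downstream.
#'
#' @inheritParams assess_promoter
#' @return An object of class `lesion_report`: a list with `species_id`,
#'   `start_codons` (see [scan_start_codons()]), `promoter_status`,
#'   `donor_intact`, `region_absent`, `lesions` (data frame) and
#'   `coverage_flag`.
#' @export
build_feature_report <- function(aln, row, indel_min_bp = 30L, absent_frac = 0.9) {
  x <- .resolve_row(aln, row)
  ann <- x$ann

  region_cols <- which(x$ref != "-")
  region_cols <- region_cols[region_cols >= ann$promoter_block[1L] &
                             region_cols <= ann$donor_pos + 1L]
  if (all(x$row[region_cols] == "-")) {
    rep <- list(
      species_id = row,
      start_codons = list(
        list(which = 1L, observed_codon = "---", intact = FALSE, kozak_class = NA_character_),
        list(which = 2L, observed_codon = "---", intact = FALSE, kozak_class = NA_character_)
      ),
      promoter_status = "absent",
      donor_intact = FALSE,
      region_absent = TRUE,
      lesions = .lesion("region_absent", ann$promoter_block[1L], ann$donor_pos + 1L,
                        length(region_cols), "whole region absent"),
      coverage_flag = x$coverage
    )
    class(rep) <- "lesion_report"
    return(rep)
  }

  prom <- assess_promoter(aln, row, indel_min_bp = indel_min_bp, absent_frac = absent_frac)
  donor <- check_splice_donor(aln, row)
  starts <- scan_start_codons(aln, row)
  orf <- detect_orf_disruptions(aln, row)

  lesions <- rbind(prom$lesions, donor$lesions, orf)
  for (s in starts) {
    if (isFALSE(s$intact)) {
      pos <- if (s$which == 1L) ann$atg1_pos else ann$atg2_pos
      cols <- .ref_base_cols(x$ref, pos, 3L)
      lesions <- rbind(lesions, .lesion(
        paste0("start", s$which, "_loss"), cols[1L], cols[3L], 3L,
        paste0("ATG", s$which, " reads ", s$observed_codon)
      ))
    }
  }
  lesions <- lesions[order(lesions$start, lesions$type), , drop = FALSE]
  rownames(lesions) <- NULL

  rep <- list(
    species_id = row,
    start_codons = starts,
    promoter_status = prom$status,
    donor_intact = donor$intact,
    region_absent = any(lesions$type == "region_absent"),
    lesions = lesions,
    coverage_flag = x$coverage
  )
  class(rep) <- "lesion_report"
  rep
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("Lesion report for %s%s\n", x$species_id,
              if (x$coverage_flag) " [low coverage]" else ""))
  s <- vapply(x$start_codons, function(s) {
    sprintf("ATG%d=%s(%s)", s$which, s$observed_codon,
            if (isTRUE(s$intact)) paste0("intact, ", .kz_or(s$kozak_class)) else
              if (is.na(s$intact)) "ambiguous" else "mutated")
  }, character(1))
  cat("  ", paste(s, collapse = "  "), "\n")
  cat(sprintf("  promoter: %s  donor: %s\n", x$promoter_status,
              if (isTRUE(x$donor_intact)) "intact" else if (is.na(x$donor_intact)) "ambiguous" else "lost"))
  if (nrow(x$lesions)) {
    cat(sprintf("  %d lesion(s):\n", nrow(x$lesions)))
    print(x$lesions, row.names = FALSE)
  } else {
    cat("  no lesions\n")
  }
  invisible(x)
}

.kz_or <- function(x) if (is.na(x)) "unscored" else x

#' Build lesion reports for every species of an alignment
#'
#' @inheritParams assess_promoter
#' @param include_reference keep the reference row's (empty) report;
#'   default `TRUE`.
#' @return A named list of `lesion_report` objects.
#' @export
build_feature_reports <- function(aln, indel_min_bp = 30L, absent_frac = 0.9,
                                  include_reference = TRUE) {
  sp <- names(aln$seqs)
  if (!include_reference) sp <- sp[-1L]
  stats::setNames(
    lapply(sp, function(s) build_feature_report(aln, s, indel_min_bp, absent_frac)),
    sp
  )
}
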