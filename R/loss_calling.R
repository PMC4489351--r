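#' Call the functionality of the alternative first exon in one species
#'
#' Converts a [build_feature_report()] into a functional / lost / unknown
#' verdict. The exon is called lost when the promoter is rearranged or
#' absent, the splice donor is not intact, both start codons are mutated, any
#' frameshift indel or premature stop disrupts the coding block, or the whole
#' region is absent. A species with only one mutated start codon remains
#' functional, initiating at the surviving ATG (ATG2 alone is a potent
#' initiator). Low-coverage rows, and rows whose verdict hinges on an
#' ambiguous (`N`) base, are unknown.
#'
#' @param report a `lesion_report`.
#' @return A list of class `functionality_call` with `species_id`, `state`
#'   (`"functional"`, `"lost"` or `"unknown"`), `reasons` (character vector;
#'   `"intact"` for clean functional calls) and `initiation_site` (1, 2 or
#'   `NA`).
#' @export
call_functionality <- function(report) {
  stopifnot(inherits(report, "lesion_report"))
  out <- function(state, reasons, site = NA_integer_) {
    structure(
      list(species_id = report$species_id, state = state,
           reasons = reasons, initiation_site = site),
      class = "functionality_call"
    )
  }
  if (report$coverage_flag)
    return(out("unknown", "low coverage"))

  s1 <- report$start_codons[[1L]]$intact
  s2 <- report$start_codons[[2L]]$intact
  reasons <- character(0)
  if (report$region_absent)
    reasons <- c(reasons, "region_absent")
  if (!is.na(report$promoter_status) && report$promoter_status %in% c("rearranged", "absent"))
    reasons <- c(reasons, paste0("promoter_", report$promoter_status))
  if (isFALSE(report$donor_intact))
    reasons <- c(reasons, "donor_loss")
  if (isFALSE(s1) && isFALSE(s2))
    reasons <- c(reasons, "both_start_codons_lost")
  disrupt <- report$lesions$type %in% c("frameshift_indel", "premature_stop")
  if (any(disrupt)) {
    reasons <- c(reasons, sprintf(
      "%s@%d-%d", report$lesions$type[disrupt],
      report$lesions$start[disrupt], report$lesions$end[disrupt]
    ))
  }
  if (length(reasons))
    return(out("lost", reasons))

  ambiguous <- is.na(report$donor_intact) || is.na(report$promoter_status) ||
    (is.na(s1) && !isTRUE(s2)) || (is.na(s2) && !isTRUE(s1))
  if (ambiguous)
    return(out("unknown", "ambiguous base at a scored feature"))
  if (!isTRUE(s1) && !isTRUE(s2))
    return(out("unknown", "no intact start codon resolved"))
  out("functional", "intact", site = if (isTRUE(s1)) 1L else 2L)
}

#' @export
print.functionality_call <- function(x, ...) {
  cat(sprintf("%s: %s", x$species_id, x$state))
  if (x$state == "functional")
    cat(sprintf(" (initiation at ATG%d)", x$initiation_site))
  if (x$state == "lost")
    cat(" [", paste(x$reasons, collapse = "; "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Call functionality for a set of species
#'
#' @param reports a named list of `lesion_report` objects
#'   (see [build_feature_reports()]).
#' @return A data frame with one row per species: `species`, `state`,
#'   `initiation_site`, `reasons` (`;`-joined).
#' @export
call_all <- function(reports) {
  ids <- vapply(reports, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) stop("duplicate species in reports")
  calls <- lapply(reports, call_functionality)
  data.frame(
    species = ids,
    state = vapply(calls, `[[`, character(1), "state"),
    initiation_site = vapply(calls, `[[`, integer(1), "initiation_site"),
    reasons = vapply(calls, function(x) paste(x$reasons, collapse = ";"), character(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Export calls as a presence/absence character matrix
#'
#' Writes the functional/lost/unknown calls as a one-character-per-species
#' 1/0/? matrix in Nexus format for interoperability with phylogenetic tools
#' (1 = exon present/functional, 0 = lost, ? = unknown).
#'
#' @param calls the data frame from [call_all()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(calls, path) {
  code <- c(functional = "1", lost = "0", unknown = "?")
  chars <- as.list(code[calls$state])
  names(chars) <- calls$species
  ape::write.nexus.data(chars, path, format = "standard", interleaved = FALSE)
  invisible(path)
}
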