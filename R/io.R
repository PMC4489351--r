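#' Flatten lesion reports to a table / rebuild them from one
#'
#' The on-disk report format is a TSV with one row per scored feature and one
#' row per lesion: columns `species`, `feature` (`promoter`, `donor`, `atg1`,
#' `atg2`, `coverage` or `lesion`), `status`, `lesion_type`, `start`, `end`,
#' `length_bp`, `detail`. Coordinates are 1-based inclusive alignment
#' columns. `reports_to_table()` and `table_to_reports()` are exact inverses
#' for the fields the downstream stages consume.
#'
#' @param reports a named list of `lesion_report` objects.
#' @return `reports_to_table()` returns a data frame.
#' @export
reports_to_table <- function(reports) {
  one <- function(rep) {
    feat <- function(feature, status, detail = "") {
      data.frame(species = rep$species_id, feature = feature, status = status,
                 lesion_type = "", start = NA_integer_, end = NA_integer_,
                 length_bp = NA_integer_, detail = detail,
                 stringsAsFactors = FALSE)
    }
    tri <- function(x, yes, no) if (is.na(x)) "unknown" else if (x) yes else no
    rows <- rbind(
      feat("promoter", if (is.na(rep$promoter_status)) "unknown" else rep$promoter_status),
      feat("donor", tri(rep$donor_intact, "intact", "lost")),
      feat("atg1", tri(rep$start_codons[[1L]]$intact, "intact", "mutated"),
           detail = paste0(rep$start_codons[[1L]]$observed_codon,
                           .kz_suffix(rep$start_codons[[1L]]$kozak_class))),
      feat("atg2", tri(rep$start_codons[[2L]]$intact, "intact", "mutated"),
           detail = paste0(rep$start_codons[[2L]]$observed_codon,
                           .kz_suffix(rep$start_codons[[2L]]$kozak_class))),
      feat("coverage", if (rep$coverage_flag) "flagged" else "ok")
    )
    if (nrow(rep$lesions)) {
      les <- data.frame(
        species = rep$species_id, feature = "lesion", status = "",
        lesion_type = rep$lesions$type, start = rep$lesions$start,
        end = rep$lesions$end, length_bp = rep$lesions$length_bp,
        detail = rep$lesions$detail, stringsAsFactors = FALSE
      )
      rows <- rbind(rows, les)
    }
    rows
  }
  out <- do.call(rbind, lapply(reports, one))
  rownames(out) <- NULL
  out
}

.kz_suffix <- function(kz) if (is.na(kz)) "" else paste0(" kozak=", kz)

#' @rdname reports_to_table
#' @param tab a data frame in the layout written by [reports_to_table()].
#' @export
table_to_reports <- function(tab) {
  needed <- c("species", "feature", "status", "lesion_type", "start", "end",
              "length_bp", "detail")
  if (!all(needed %in% names(tab)))
    stop("report table is missing columns: ",
         paste(setdiff(needed, names(tab)), collapse = ", "))
  split_tab <- split(tab, tab$species)
  reports <- lapply(split_tab, function(d) {
    g <- function(feature) d[d$feature == feature, , drop = FALSE][1L, ]
    tri <- function(status, yes) if (status == "unknown") NA else status == yes
    codon_of <- function(detail) sub(" kozak=.*$", "", detail)
    kz_of <- function(detail) {
      if (grepl(" kozak=", detail)) sub("^.* kozak=", "", detail) else NA_character_
    }
    start_codons <- lapply(c(1L, 2L), function(w) {
      r <- g(paste0("atg", w))
      list(which = w, observed_codon = codon_of(r$detail),
           intact = tri(r$status, "intact"), kozak_class = kz_of(r$detail))
    })
    les <- d[d$feature == "lesion", , drop = FALSE]
    lesions <- if (nrow(les)) {
      data.frame(type = les$lesion_type, start = as.integer(les$start),
                 end = as.integer(les$end), length_bp = as.integer(les$length_bp),
                 detail = les$detail, stringsAsFactors = FALSE)
    } else .empty_lesions()
    rep <- list(
      species_id = d$species[1L],
      start_codons = start_codons,
      promoter_status = {
        s <- g("promoter")$status
        if (s == "unknown") NA_character_ else s
      },
      donor_intact = tri(g("donor")$status, "intact"),
      region_absent = any(lesions$type == "region_absent"),
      lesions = lesions,
      coverage_flag = g("coverage")$status == "flagged"
    )
    class(rep) <- "lesion_report"
    rep
  })
  # preserve first-appearance order
  reports[unique(tab$species)]
}

#' Read / write the TSV formats used between pipeline stages
#'
#' Lesion reports, functionality calls, loss events and expression calls all
#' travel as plain TSV with a header row.
#'
#' @param x the object to write (report table, calls, events or expression
#'   data frame).
#' @param path file path.
#' @return The read functions return a data frame (or, for
#'   `read_lesion_reports()`, a named list of `lesion_report`s); the write
#'   functions return `path` invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", quote = "", comment.char = "",
                    colClasses = NA, check.names = FALSE, fill = TRUE,
                    blank.lines.skip = TRUE)
}

#' @rdname write_tsv
#' @param reports a named list of `lesion_report`s.
#' @export
write_lesion_reports <- function(reports, path) {
  write_tsv(reports_to_table(reports), path)
}

#' @rdname write_tsv
#' @export
read_lesion_reports <- function(path) {
  tab <- read_tsv(path)
  tab$detail[is.na(tab$detail)] <- ""
  tab$lesion_type[is.na(tab$lesion_type)] <- ""
  tab$status[is.na(tab$status)] <- ""
  table_to_reports(tab)
}
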