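#' Reporter construct for the scanning model
#'
#' An mRNA, 5' to 3', consisting of a native 5'UTR, an exon-1A-derived
#' segment, and a downstream reporter open reading frame fused in frame. The
#' reporter's own first in-frame ATG marks the boundary: candidate sites
#' upstream of it belong to the exon segment, sites at or beyond it are
#' internal reporter sites.
#'
#' @param sequence nucleotide string (`U` is converted to `T`).
#' @param reporter_start 1-based position of the A of the reporter's first
#'   in-frame ATG.
#' @param label construct name.
#' @return An object of class `reporter_construct`.
#' @export
reporter_construct <- function(sequence, reporter_start, label = "construct") {
  sequence <- chartr("u", "t", toupper(sequence))
  sequence <- chartr("U", "T", sequence)
  if (grepl("[^ACGT]", sequence))
    stop("construct sequence must be over A,C,G,T/U")
  reporter_start <- as.integer(reporter_start)
  if (reporter_start < 1L || reporter_start + 2L > nchar(sequence))
    stop("reporter_start out of range")
  if (substr(sequence, reporter_start, reporter_start + 2L) != "ATG")
    stop("no ATG at reporter_start")
  structure(
    list(sequence = sequence, reporter_start = reporter_start, label = label),
    class = "reporter_construct"
  )
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat(sprintf("Construct '%s': %d nt, reporter ATG at %d\n",
              x$label, nchar(x$sequence), x$reporter_start))
  invisible(x)
}

# codons exactly one substitution away from ATG
.near_cognates <- local({
  out <- character(0)
  for (i in 1:3) for (b in c("A", "C", "G", "T")) {
    codon <- "ATG"
    substr(codon, i, i) <- b
    if (codon != "ATG") out <- c(out, codon)
  }
  unique(out)
})

#' Scan a construct for candidate initiation sites
#'
#' A 5' to 3' scan over every position of the sequence. Candidates are all
#' ATG codons, plus near-cognate codons (exactly one substitution away from
#' ATG, e.g. AAG) whose Kozak context is strong - near-cognates initiate
#' measurably only in an optimal context.
#'
#' @param construct a [reporter_construct()].
#' @return A data frame ordered 5' to 3': `position`, `codon`, `is_atg`,
#'   `kozak_class` (for ATGs; truncation-aware), `in_frame` (same frame as
#'   the reporter), `region` (`"upstream"` or `"reporter"`).
#' @export
find_candidate_sites <- function(construct) {
  stopifnot(inherits(construct, "reporter_construct"))
  s <- construct$sequence
  n <- nchar(s)
  pos <- seq_len(n - 2L)
  codons <- substring(s, pos, pos + 2L)
  kz <- function(p) {
    lo <- max(1L, p - 6L)
    hi <- min(n, p + 5L)
    window <- substr(s, lo, hi)
    score_kozak(window, atg_at = p - lo + 1L)
  }
  is_atg <- codons == "ATG"
  is_nc <- codons %in% .near_cognates
  keep <- which(is_atg)
  for (p in pos[is_nc]) {
    # a near-cognate is only a candidate in a strong context; borrow the
    # Kozak scorer by substituting an ATG at the site
    tmp <- s
    substr(tmp, p, p + 2L) <- "ATG"
    lo <- max(1L, p - 6L)
    hi <- min(nchar(tmp), p + 5L)
    if (identical(score_kozak(substr(tmp, lo, hi), atg_at = p - lo + 1L), "strong"))
      keep <- c(keep, p)
  }
  keep <- sort(unique(keep))
  if (!length(keep)) {
    return(data.frame(position = integer(0), codon = character(0),
                      is_atg = logical(0), kozak_class = character(0),
                      in_frame = logical(0), region = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    position = keep,
    codon = codons[keep],
    is_atg = is_atg[keep],
    kozak_class = vapply(keep, function(p) {
      if (codons[p] == "ATG") kz(p) else "strong"
    }, character(1)),
    in_frame = (keep - construct$reporter_start) %% 3L == 0L,
    region = ifelse(keep >= construct$reporter_start, "reporter", "upstream"),
    stringsAsFactors = FALSE
  )
}

#' Predict the translation products of a reporter construct
#'
#' Encodes the ribosomal scanning logic validated by in vitro translation of
#' first-exon reporter fusions:
#' \itemize{
#'   \item the 5'-most intact ATG of the exon segment gives a `strong`
#'     product; ribosomes initiating there suppress all downstream
#'     non-specific initiation;
#'   \item further in-frame ATGs of the exon segment give `leaky` products
#'     (ribosomes that scanned past the first site);
#'   \item near-cognate sites (strong context only) give `faint` products,
#'     and internal reporter ATGs give `background` products, but only when
#'     the exon segment retains no intact ATG at all.
#' }
#'
#' @inheritParams find_candidate_sites
#' @return A data frame: `position`, `codon`, `strength` (`strong`, `leaky`,
#'   `faint`, `background`), `in_frame`.
#' @export
predict_products <- function(construct) {
  sites <- find_candidate_sites(construct)
  up <- sites[sites$region == "upstream", , drop = FALSE]
  up_atg <- up[up$is_atg, , drop = FALSE]

  prod <- function(d, strength) {
    if (!nrow(d)) return(NULL)
    data.frame(position = d$position, codon = d$codon, strength = strength,
               in_frame = d$in_frame, stringsAsFactors = FALSE)
  }
  out <- NULL
  if (nrow(up_atg)) {
    first <- up_atg[which.min(up_atg$position), , drop = FALSE]
    out <- rbind(out, prod(first, "strong"))
    later <- up_atg[up_atg$position > first$position & up_atg$in_frame, , drop = FALSE]
    out <- rbind(out, prod(later, "leaky"))
  } else {
    nc <- up[!up$is_atg, , drop = FALSE]
    out <- rbind(out, prod(nc, "faint"))
    internal <- sites[sites$region == "reporter" & sites$is_atg, , drop = FALSE]
    out <- rbind(out, prod(internal, "background"))
  }
  if (is.null(out)) {
    out <- data.frame(position = integer(0), codon = character(0),
                      strength = character(0), in_frame = logical(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$position), , drop = FALSE]
}

#' Order predicted products by size
#'
#' Every product runs to the reporter's stop (the last in-frame stop codon,
#' or the 3' end if none), so earlier initiation sites give longer products.
#' Two sites 3 codons apart give products differing by exactly 3 residues.
#'
#' @param products a data frame from [predict_products()].
#' @inheritParams find_candidate_sites
#' @return `products` with added `residues` (product length in amino acids,
#'   counting from the initiation site) and `length_rank` (1 = longest).
#' @export
product_lengths <- function(products, construct) {
  stopifnot(inherits(construct, "reporter_construct"))
  if (!nrow(products)) {
    products$residues <- integer(0)
    products$length_rank <- integer(0)
    return(products)
  }
  s <- construct$sequence
  n <- nchar(s)
  # reporter stop: last stop codon in the reporter frame
  frame_pos <- seq(construct$reporter_start, n - 2L, by = 3L)
  codons <- substring(s, frame_pos, frame_pos + 2L)
  stop_at <- frame_pos[codons %in% c("TAA", "TAG", "TGA")]
  stop_pos <- if (length(stop_at)) max(stop_at) else n + 1L
  products$residues <- (stop_pos - products$position) %/% 3L
  products$length_rank <- rank(-products$residues, ties.method = "min")
  products[order(products$length_rank), , drop = FALSE]
}
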