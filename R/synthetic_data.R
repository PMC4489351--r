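#' Reference template of the exon-1A-like region
#'
#' A fully annotated, deterministic reference sequence used by the
#' simulators and the packaged worked-example fixture: a 440-bp promoter
#' block, an 80-bp conserved TSS block, a 40-bp 5'UTR ending in an optimal
#' Kozak context, a 90-bp coding block carrying two in-frame ATGs (30 bp
#' apart, both in strong context) and no in-frame stop, and a canonical GT
#' splice donor followed by a short intronic tail. Total width 660 columns.
#'
#' @return A list with `sequence` (character, ungapped), `annotation`
#'   (a [feature_annotation()]) and `protected_cols` (columns that the
#'   neutral-evolution simulator must not touch so that background
#'   divergence can never masquerade as a lesion).
#' @export
region_template <- function() {
  promoter <- strrep("CTAGACCTGA", 44L) # 440
  tss <- strrep("GGCTCTCCAA", 8L) # 80
  utr5 <- paste0(strrep("CTTCCTTCTC", 3L), "CTCCGCCACC") # 40
  coding <- paste0(
    "ATGGTCACCAAGGACCTCCACTCCACCACCATGGAG", # codons 1-12, ATG1 + ATG2
    strrep("GACCTGGAATCCGTGCAAGCTTTC", 2L), # codons 13-28
    "GGAGGA" # codons 29-30
  ) # 90
  intron <- "GTAAGTACCT" # 10, donor GT first
  sequence <- paste0(promoter, tss, utr5, coding, intron)
  stopifnot(nchar(sequence) == 660L)
  ann <- feature_annotation(
    promoter_block = c(1L, 440L), tss_block = c(441L, 520L),
    atg1_pos = 561L, atg2_pos = 591L,
    coding_block = c(561L, 650L), donor_pos = 651L,
    width = 660L
  )
  protected <- sort(unique(c(
    561L:652L, # coding block + donor dinucleotide
    558L # Kozak -3 of ATG1 (the only scored context base outside the block)
  )))
  list(sequence = sequence, annotation = ann, protected_cols = protected)
}

#' Simulate a rooted binary species tree
#'
#' Thin reproducible wrapper around [ape::rtree()] for a mammal-like random
#' topology with branch lengths.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed; same seed, same Newick string.
#' @return A rooted `phylo` with `n_taxa` leaves and `n_taxa - 1` internal
#'   nodes.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  set.seed(seed)
  ape::rtree(n_taxa, rooted = TRUE)
}

#' Evolve the template region along a tree by neutral point substitution
#'
#' Applies point substitutions only (alignment columns are preserved) along
#' each branch, with per-site substitution probability
#' `1 - exp(-sub_rate * branch_length)`. Annotated feature positions listed
#' in the template's `protected_cols` are never touched, so background
#' divergence cannot spontaneously create a lesion and planted truth tables
#' stay exact; pass `protect = FALSE` for an unprotected stress-test mode.
#'
#' @param template a [region_template()]-like list.
#' @param tree a rooted `phylo` with branch lengths.
#' @param sub_rate expected substitutions per site per unit branch length.
#' @param seed integer seed.
#' @param protect protect annotated feature positions (default `TRUE`).
#' @return A [region_alignment()] whose first row (`Reference`) is the
#'   template and remaining rows are the tree's leaves.
#' @export
evolve_region <- function(template, tree, sub_rate = 0.05, seed = 1L,
                          protect = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  set.seed(seed)
  ref <- .aln_chars(template$sequence)
  w <- length(ref)
  free <- if (protect) setdiff(seq_len(w), template$protected_cols) else seq_len(w)
  bases <- c("A", "C", "G", "T")

  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- ref
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    p <- pre$edge[i, 1L]; ch <- pre$edge[i, 2L]
    s <- seqs[[p]]
    pr <- 1 - exp(-sub_rate * pre$edge.length[i])
    hit <- free[stats::runif(length(free)) < pr]
    for (col in hit) {
      s[col] <- sample(setdiff(bases, s[col]), 1L)
    }
    seqs[[ch]] <- s
  }
  rows <- c(
    list(Reference = template$sequence),
    stats::setNames(
      lapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = "")),
      tree$tip.label
    )
  )
  region_alignment(unlist(rows), template$annotation)
}

#' Specify a lesion to plant on a tree branch
#'
#' A lesion is planted on the stem branch of the clade spanned by `clade`
#' (a single leaf name, or several names whose MRCA stem is used) and is
#' inherited identically by every descendant leaf.
#'
#' @param clade character vector of leaf labels.
#' @param type one of `promoter_deletion`, `promoter_insertion`,
#'   `donor_loss`, `start1_loss`, `start2_loss`, `frameshift_indel`,
#'   `premature_stop`, `region_absent`.
#' @param start alignment column (template coordinates) where the lesion
#'   starts; for insertions, the column after which the segment is inserted.
#'   Sensible defaults per type are filled in by [plant_lesions()].
#' @param length_bp lesion length where meaningful (deletions, insertions,
#'   frameshifts).
#' @param seq replacement/insert sequence for substitution and insertion
#'   lesions.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(clade, type, start = NULL, length_bp = NULL, seq = NULL) {
  types <- c("promoter_deletion", "promoter_insertion", "donor_loss",
             "start1_loss", "start2_loss", "frameshift_indel",
             "premature_stop", "region_absent")
  if (!type %in% types) stop("unknown lesion type: ", type)
  structure(
    list(clade = clade, type = type,
         start = if (is.null(start)) NULL else as.integer(start),
         length_bp = if (is.null(length_bp)) NULL else as.integer(length_bp),
         seq = seq),
    class = "lesion_spec"
  )
}

.spec_defaults <- function(spec, ann) {
  d <- spec
  if (is.null(d$start)) {
    d$start <- switch(
      d$type,
      promoter_deletion = ann$tss_block[1L],
      promoter_insertion = ann$tss_block[1L] + 39L,
      donor_loss = ann$donor_pos,
      start1_loss = ann$atg1_pos,
      start2_loss = ann$atg2_pos,
      premature_stop = ann$atg1_pos + 12L, # codon 5
      frameshift_indel = ann$atg1_pos + 79L,
      region_absent = 1L
    )
  }
  if (is.null(d$length_bp)) {
    d$length_bp <- switch(
      d$type,
      promoter_deletion = ann$tss_block[2L] - ann$tss_block[1L] + 1L,
      promoter_insertion = 72L,
      frameshift_indel = 2L,
      donor_loss = 2L, start1_loss = 3L, start2_loss = 3L,
      premature_stop = 3L, region_absent = NA_integer_
    )
  }
  if (is.null(d$seq)) {
    d$seq <- switch(
      d$type,
      promoter_insertion = strrep("ACGGTCCTTAGC", 6L),
      donor_loss = "AT",
      start1_loss = "ACG", start2_loss = "ACG",
      premature_stop = "TGA",
      NULL
    )
  }
  d
}

.spec_leaves <- function(spec, tree) {
  miss <- setdiff(spec$clade, tree$tip.label)
  if (length(miss)) stop("lesion_spec clade leaf not in tree: ", miss[1])
  if (length(spec$clade) == 1L) return(spec$clade)
  .tips_below(tree, ape::getMRCA(tree, spec$clade))
}

# is the spec set planted on one branch sufficient, on its own, to abolish
# the exon? (mirrors the loss-calling rules)
.specs_cause_loss <- function(specs, ann) {
  types <- vapply(specs, `[[`, character(1), "type")
  if (any(types %in% c("donor_loss", "premature_stop", "region_absent")))
    return(TRUE)
  for (d in specs) {
    if (d$type == "frameshift_indel" && d$length_bp %% 3L != 0L) return(TRUE)
    if (d$type == "promoter_deletion" && d$length_bp >= 30L &&
        d$start <= ann$tss_block[2L] && d$start + d$length_bp - 1L >= ann$tss_block[1L])
      return(TRUE)
    if (d$type == "promoter_insertion" && nchar(d$seq) >= 30L &&
        d$start >= ann$tss_block[1L] && d$start < ann$tss_block[2L])
      return(TRUE)
  }
  all(c("start1_loss", "start2_loss") %in% types)
}

#' Plant lesion events on a tree and apply them to an alignment
#'
#' Each [lesion_spec()] is applied identically to every leaf descending from
#' its branch: substitutions overwrite columns, deletions turn columns into
#' gaps, insertions add new alignment columns (gap characters in all other
#' rows; the annotation's coordinates are shifted accordingly), and
#' `region_absent` gaps the entire row. The returned truth table records the
#' expected per-leaf functionality call and the expected number of
#' independent loss events (one per planted branch whose own lesion set is
#' loss-causing).
#'
#' @param aln a [region_alignment()] (e.g. from [evolve_region()]) whose
#'   annotation is still in template coordinates.
#' @param tree the tree whose leaves name the alignment rows.
#' @param specs list of [lesion_spec()]s.
#' @return A list with `alignment` (lesioned, annotation shifted for any
#'   insertions) and `truth` (list with `leaf_states` data frame,
#'   `expected_events`, and `branches`, the per-branch spec summary).
#' @export
plant_lesions <- function(aln, tree, specs) {
  stopifnot(inherits(aln, "region_alignment"))
  ann <- aln$annotation
  specs <- lapply(specs, function(s) {
    stopifnot(inherits(s, "lesion_spec"))
    .spec_defaults(s, ann)
  })
  leaves_of <- lapply(specs, .spec_leaves, tree = tree)
  branch_key <- vapply(leaves_of, function(x) paste(sort(x), collapse = ","),
                       character(1))

  # contradictory overlap guard: two specs on leaf-sharing branches may not
  # rewrite the same columns unless they are the same spec. Insertions add
  # columns rather than rewriting them and region_absent subsumes anything,
  # so both are exempt.
  n <- length(specs)
  span_of <- function(d) {
    len <- if (!is.null(d$seq)) nchar(d$seq) else d$length_bp
    c(d$start, d$start + max(len - 1L, 0L))
  }
  rewrites <- function(d) !d$type %in% c("promoter_insertion", "region_absent")
  if (n > 1L) {
    for (a in seq_len(n)) for (b in seq_len(a - 1L)) {
      if (!rewrites(specs[[a]]) || !rewrites(specs[[b]])) next
      if (!length(intersect(leaves_of[[a]], leaves_of[[b]]))) next
      sa <- span_of(specs[[a]]); sb <- span_of(specs[[b]])
      same <- identical(specs[[a]][c("type", "start", "length_bp", "seq")],
                        specs[[b]][c("type", "start", "length_bp", "seq")])
      if (!same && sa[1L] <= sb[2L] && sa[2L] >= sb[1L])
        stop("overlapping contradictory lesion specs on intersecting clades")
    }
  }

  rows <- lapply(aln$seqs, .aln_chars)
  width <- length(rows[[1L]])

  # pass 1: substitutions, deletions, whole-region loss (template coords)
  for (i in seq_along(specs)) {
    d <- specs[[i]]
    targets <- intersect(names(rows), leaves_of[[i]])
    for (sp in targets) {
      if (d$type %in% c("donor_loss", "start1_loss", "start2_loss", "premature_stop")) {
        cols <- d$start:(d$start + nchar(d$seq) - 1L)
        rows[[sp]][cols] <- .aln_chars(d$seq)
      } else if (d$type %in% c("promoter_deletion", "frameshift_indel")) {
        cols <- d$start:(d$start + d$length_bp - 1L)
        rows[[sp]][cols] <- "-"
      } else if (d$type == "region_absent") {
        rows[[sp]][] <- "-"
      }
    }
  }

  # pass 2: insertions, processed at descending positions so earlier
  # template coordinates stay valid
  ins <- Filter(function(d) d$type == "promoter_insertion", specs)
  ins_leaves <- leaves_of[vapply(specs, `[[`, character(1), "type") == "promoter_insertion"]
  if (length(ins)) {
    ord <- order(vapply(ins, `[[`, integer(1), "start"), decreasing = TRUE)
    for (k in ord) {
      d <- ins[[k]]
      seg <- .aln_chars(d$seq)
      gap <- rep("-", length(seg))
      targets <- ins_leaves[[k]]
      spliced <- lapply(names(rows), function(sp) {
        r <- rows[[sp]]
        c(r[seq_len(d$start)], if (sp %in% targets) seg else gap,
          if (d$start < length(r)) r[(d$start + 1L):length(r)] else character(0))
      })
      rows <- stats::setNames(spliced, names(rows))
    }
    # shift the annotation through all insertions
    starts <- vapply(ins, `[[`, integer(1), "start")
    lens <- vapply(ins, function(d) nchar(d$seq), integer(1))
    shift_pos <- function(p) p + sum(lens[starts < p])
    shift_block <- function(b) c(shift_pos(b[1L]), b[2L] + sum(lens[starts < b[2L]]))
    ann <- feature_annotation(
      promoter_block = shift_block(ann$promoter_block),
      tss_block = shift_block(ann$tss_block),
      atg1_pos = shift_pos(ann$atg1_pos),
      atg2_pos = shift_pos(ann$atg2_pos),
      coding_block = shift_block(ann$coding_block),
      donor_pos = shift_pos(ann$donor_pos)
    )
  }

  lesioned <- region_alignment(
    vapply(rows, paste, character(1), collapse = ""),
    ann,
    coverage_flag = aln$coverage_flag
  )

  # truth table
  by_branch <- split(specs, branch_key)
  branch_leaves <- lapply(split(leaves_of, branch_key), `[[`, 1L)
  causes <- vapply(by_branch, .specs_cause_loss, logical(1), ann = aln$annotation)
  leaf_specs <- stats::setNames(vector("list", length(tree$tip.label)), tree$tip.label)
  for (i in seq_along(specs)) {
    for (sp in leaves_of[[i]])
      leaf_specs[[sp]] <- c(leaf_specs[[sp]], list(specs[[i]]))
  }
  leaf_state <- vapply(tree$tip.label, function(sp) {
    if (!length(leaf_specs[[sp]])) return("functional")
    if (.specs_cause_loss(leaf_specs[[sp]], aln$annotation)) "lost" else "functional"
  }, character(1))
  leaf_state[names(lesioned$coverage_flag)[lesioned$coverage_flag]] <- "unknown"

  truth <- list(
    leaf_states = data.frame(species = tree$tip.label,
                             state = unname(leaf_state[tree$tip.label]),
                             stringsAsFactors = FALSE),
    expected_events = sum(causes & vapply(branch_leaves, length, integer(1)) > 0L),
    branches = data.frame(
      branch = names(by_branch),
      n_specs = vapply(by_branch, length, integer(1)),
      causes_loss = unname(causes),
      stringsAsFactors = FALSE
    )
  )
  list(alignment = lesioned, truth = truth)
}

#' Simulate a full loss scenario with known ground truth
#'
#' Draws a random rooted tree, evolves the template region along it with
#' protected neutral substitutions, and plants `n_events` independent
#' loss-causing lesion events on disjoint branches, each with a distinct
#' lesion signature, leaving at least one leaf intact. Used to verify that
#' the feature -> call -> Dollo-mapping pipeline recovers the planted number
#' of events and the per-leaf calls exactly.
#'
#' @param n_taxa number of leaves (default 12).
#' @param n_events number of planted independent losses, 1-7.
#' @param sub_rate background substitution rate (default 0.05).
#' @param seed integer seed.
#' @return A list with `tree`, `alignment`, `truth` (see [plant_lesions()])
#'   and `specs`.
#' @export
simulate_loss_scenario <- function(n_taxa = 12L, n_events = 3L,
                                   sub_rate = 0.05, seed = 1L) {
  if (n_events < 1L || n_events > 7L) stop("n_events must be in 1..7")
  if (n_taxa < n_events + 1L) stop("need at least n_events + 1 leaves")
  tree <- simulate_tree(n_taxa, seed = seed)
  tpl <- region_template()
  aln <- evolve_region(tpl, tree, sub_rate = sub_rate, seed = seed + 1L)

  set.seed(seed + 2L)
  ann <- tpl$annotation
  kinds <- list(
    function(cl) list(lesion_spec(cl, "promoter_deletion"),
                      lesion_spec(cl, "promoter_insertion")),
    function(cl) list(lesion_spec(cl, "donor_loss")),
    function(cl) list(lesion_spec(cl, "region_absent")),
    function(cl) list(lesion_spec(cl, "frameshift_indel",
                                  start = ann$atg1_pos + 79L, length_bp = 2L)),
    function(cl) list(lesion_spec(cl, "frameshift_indel",
                                  start = ann$atg1_pos + 49L, length_bp = 1L)),
    function(cl) list(lesion_spec(cl, "premature_stop")),
    function(cl) list(lesion_spec(cl, "start1_loss"), lesion_spec(cl, "start2_loss"))
  )
  kind_ids <- sample(seq_along(kinds), n_events)

  # choose disjoint clades, keeping at least one leaf functional and
  # reserving one leaf for every event still to be placed
  ntip <- length(tree$tip.label)
  nodes <- sample((ntip + 2L):(ntip + tree$Nnode), tree$Nnode - 1L)
  clades <- c(as.list(sample(tree$tip.label)),
              lapply(nodes, .tips_below, tree = tree))
  clades <- clades[sample(length(clades))]
  used <- character(0)
  chosen <- list()
  for (cl in clades) {
    if (length(chosen) == n_events) break
    if (length(intersect(cl, used))) next
    still_needed <- n_events - length(chosen) - 1L
    if (length(used) + length(cl) + still_needed > ntip - 1L) next
    chosen <- c(chosen, list(cl))
    used <- union(used, cl)
  }
  for (leaf in sample(setdiff(tree$tip.label, used))) {
    if (length(chosen) == n_events) break
    if (length(used) + 1L > ntip - 1L) break
    chosen <- c(chosen, list(leaf))
    used <- union(used, leaf)
  }
  if (length(chosen) < n_events)
    stop("could not place ", n_events, " disjoint events on this tree")

  specs <- unlist(
    lapply(seq_len(n_events), function(i) kinds[[kind_ids[i]]](chosen[[i]])),
    recursive = FALSE
  )
  planted <- plant_lesions(aln, tree, specs)
  list(tree = tree, alignment = planted$alignment, truth = planted$truth,
       specs = specs)
}

#' Simulate an exon-level read-count library
#'
#' Reads for the two alternative first exons are drawn with means
#' proportional to molar level times exon length at the requested total
#' first-exon depth; the control-exon mean is set so that its per-bp density
#' equals the average first-exon density (the coherence identity the
#' consistency check tests). Counts are Poisson, or negative binomial when
#' `dispersion > 0` (`size = 1/dispersion`).
#'
#' @param molar_ratio_B_over_A molar level of isoform B relative to A; `1`
#'   is the equal-expression null, `Inf` means A absent, `0` means B absent.
#' @param depth expected total reads over the two first exons.
#' @param model an [exon_model()].
#' @param dispersion negative-binomial overdispersion (0 = Poisson).
#' @param seed integer seed.
#' @param library_id library label.
#' @return A one-row data frame: `library`, `exon_1A`, `exon_1B`, `exon_6`.
#' @export
simulate_counts <- function(molar_ratio_B_over_A = 1, depth = 5000,
                            model = exon_model(), dispersion = 0,
                            seed = 1L, library_id = "sim") {
  set.seed(seed)
  mu <- expected_counts(molar_ratio_B_over_A, depth, model)
  draw <- function(m) {
    if (m == 0) return(0L)
    if (dispersion > 0) stats::rnbinom(1L, mu = m, size = 1 / dispersion)
    else stats::rpois(1L, m)
  }
  data.frame(
    library = library_id,
    exon_1A = draw(mu[["exon_1A"]]),
    exon_1B = draw(mu[["exon_1B"]]),
    exon_6 = draw(mu[["exon_6"]]),
    stringsAsFactors = FALSE
  )
}

#' @rdname simulate_counts
#' @return `expected_counts()` returns the named vector of expected read
#'   counts; at `molar_ratio_B_over_A = 1` and `depth = 473` with the
#'   default model this is exactly the length split (228, 245, 426).
#' @export
expected_counts <- function(molar_ratio_B_over_A = 1, depth = 5000,
                            model = exon_model()) {
  stopifnot(inherits(model, "exon_model"))
  if (depth < 1) stop("depth must be >= 1")
  if (is.na(molar_ratio_B_over_A) || molar_ratio_B_over_A < 0)
    stop("molar ratio must be >= 0 (Inf allowed)")
  if (is.infinite(molar_ratio_B_over_A)) {
    mA <- 0; mB <- 1
  } else {
    mA <- 1; mB <- molar_ratio_B_over_A
  }
  wA <- mA * model$exon_1A
  wB <- mB * model$exon_1B
  muA <- depth * wA / (wA + wB)
  muB <- depth * wB / (wA + wB)
  mu6 <- model$exon_6 * (muA / model$exon_1A + muB / model$exon_1B) / 2
  c(exon_1A = muA, exon_1B = muB, exon_6 = mu6)
}

#' The seven reporter-construct archetypes
#'
#' Synthetic stand-ins for the in vitro translation constructs: a wild-type
#' first exon (two in-frame ATGs 30 nt apart, both in strong Kozak context,
#' and a near-cognate AAG 3 codons downstream of ATG1) fused in frame to a
#' reporter ORF, plus the single- and double-ATG mutants and the
#' one-ATG-species variants. In the double mutant both ATGs are replaced by
#' codons two substitutions away from ATG, so the only remaining upstream
#' candidate is the strong-context AAG.
#'
#' @return A named list of seven [reporter_construct()]s: `WT`, `mutATG1`,
#'   `mutATG2`, `double_mutant`, `Cavia`, `Equus`, `Vicugna`.
#' @export
make_archetype_constructs <- function() {
  utr5 <- paste0("CCTCCTCCTCCTCCTCCTCCTCC", "GCCACC") # 29 nt
  exon <- "ATGGTCACCAAGGACCTCCACTCCACCACCATGGAGGACTACAAAGCC" # 48 nt
  reporter <- "ATGGCTTCCAAGGTGTACGGACACATGGAGTCCGGATTCCTGGAGTAA" # 48 nt
  wt <- paste0(utr5, exon, reporter)
  rs <- nchar(utr5) + nchar(exon) + 1L # 78
  atg1 <- nchar(utr5) + 1L # 30
  atg2 <- atg1 + 30L # 60
  sub <- function(s, at, codon) {
    substr(s, at, at + 2L) <- codon
    s
  }
  list(
    WT = reporter_construct(wt, rs, "WT"),
    mutATG1 = reporter_construct(sub(wt, atg1, "ACG"), rs, "mutATG1"),
    mutATG2 = reporter_construct(sub(wt, atg2, "ACG"), rs, "mutATG2"),
    double_mutant = reporter_construct(
      sub(sub(wt, atg1, "GCG"), atg2, "GTC"), rs, "double_mutant"
    ),
    Cavia = reporter_construct(sub(wt, atg1 + 15L, "CTG"), rs, "Cavia"),
    Equus = reporter_construct(sub(wt, atg1, "ACG"), rs, "Equus"),
    Vicugna = reporter_construct(sub(wt, atg1, "ATA"), rs, "Vicugna")
  )
}

#' The packaged worked-example fixture
#'
#' A synthetic transcription of the published survey of the exon-1A region
#' across mammals: a 15-species cladogram, a reference-identical row for each
#' functional species, and the documented lesions planted per lineage — a
#' shared promoter rearrangement (80-bp TSS deletion replaced by a 72-bp
#' insertion) in the muroid clade plus mosaic coding lesions; independent
#' frameshift/stop lesions in the two octodontoid rodents; a promoter
#' deletion plus premature stop in the tenrec; whole-region absence in the
#' hedgehog; splice-donor loss in pig and shrew; and single-ATG loss in the
#' two species that initiate at ATG2. Two placeholder muroid leaves are
#' coverage-flagged (state unknown). All sequences are synthetic stand-ins
#' built from the package template; no real genomic sequence is included.
#'
#' Running the full pipeline on this fixture yields 7 independent loss
#' events (5 under plain lesion-ignorant Dollo mapping).
#'
#' @return A list with `tree` (phylo), `alignment` (a [region_alignment()],
#'   reference row first), `specs` (the planted [lesion_spec()]s), `truth`
#'   (the generator's truth table) and `expected` (list with
#'   `independent_losses = 7`, `dollo_events = 5`).
#' @export
make_fixture_fig2a <- function() {
  newick <- paste0(
    "(Macropus,(Echinops,(((Homo,Macaca),(((Ctenomys,Octodon),Cavia),",
    "((Mus,Rattus),(Meriones,(Muroid_sp1,Muroid_sp2))))),",
    "((Erinaceus,Sorex),((Sus,(Bos,Vicugna)),Equus)))));"
  )
  tree <- ape::read.tree(text = newick)
  tpl <- region_template()
  species <- tree$tip.label
  seqs <- stats::setNames(
    rep(tpl$sequence, length(species)),
    c("Homo", setdiff(species, "Homo"))
  )
  aln <- region_alignment(
    seqs, tpl$annotation,
    coverage_flag = c(Muroid_sp1 = TRUE, Muroid_sp2 = TRUE)
  )
  muroids <- c("Mus", "Rattus", "Meriones", "Muroid_sp1", "Muroid_sp2")
  ann <- tpl$annotation
  specs <- list(
    # shared muroid promoter rearrangement, ancestral to the clade
    lesion_spec(muroids, "promoter_deletion", start = 441L, length_bp = 80L),
    lesion_spec(muroids, "promoter_insertion", start = 480L),
    # mosaic degeneration after the promoter loss
    lesion_spec("Mus", "frameshift_indel", start = 610L, length_bp = 1L),
    lesion_spec("Rattus", "premature_stop", start = 618L, seq = "TAA"),
    # independent coding lesions in the octodontoid sisters
    lesion_spec("Ctenomys", "frameshift_indel", start = 640L, length_bp = 2L),
    lesion_spec("Octodon", "premature_stop", start = 573L),
    # tenrec: promoter deletion + stop
    lesion_spec("Echinops", "promoter_deletion", start = 460L, length_bp = 60L),
    lesion_spec("Echinops", "premature_stop", start = 582L),
    # hedgehog: whole region gone
    lesion_spec("Erinaceus", "region_absent"),
    # donor losses
    lesion_spec("Sus", "donor_loss", seq = "GC"),
    lesion_spec("Sorex", "donor_loss", seq = "AT"),
    # single-ATG species, still functional via ATG2
    lesion_spec("Equus", "start1_loss", seq = "ACG"),
    lesion_spec("Vicugna", "start1_loss", seq = "ATA")
  )
  planted <- plant_lesions(aln, tree, specs)
  list(
    tree = tree,
    alignment = planted$alignment,
    specs = specs,
    truth = planted$truth,
    expected = list(independent_losses = 7L, dollo_events = 5L)
  )
}
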