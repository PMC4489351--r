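#' Map isoform losses onto a rooted species tree under Dollo parsimony
#'
#' Assuming the exon was gained once at the root of the tree (Dollo
#' parsimony: a single gain, any number of irreversible losses), finds the
#' minimum set of branches such that exactly the leaves called `lost` descend
#' from a loss branch. Leaves called `unknown` are wildcards: they may sit
#' inside a lost clade without forcing an extra event, and they never anchor
#' an event themselves. Equivalently, each event is a maximal
#' lost-or-unknown-only clade containing at least one lost leaf. Among
#' equally parsimonious placements the one closest to the leaves is reported:
#' the event is anchored at the stem of the most recent common ancestor of
#' its lost leaves.
#'
#' @param tree a rooted `phylo` tree whose tip labels cover the species in
#'   `calls` (polytomies allowed). Tips absent from `calls` are treated as
#'   unknown.
#' @param calls either the data frame from [call_all()] or a named character
#'   vector of states (`"functional"`, `"lost"`, `"unknown"`).
#' @return A data frame of loss events: `event_id`, `anchor_node` (ape node
#'   number of the clade whose stem branch carries the loss), `leaves`
#'   (comma-joined lost leaves supporting the event), `n_leaves`,
#'   `shared_lesion` (filled by [split_by_lesion()]) and `flagged` (`TRUE`
#'   for the degenerate all-lost case, which contradicts presence at the
#'   root).
#' @export
dollo_events <- function(tree, calls) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("the species tree must be rooted")
  states <- .norm_calls(calls)
  ntip <- length(tree$tip.label)
  miss <- setdiff(names(states), tree$tip.label)
  if (length(miss))
    stop("species absent from the tree: ", paste(miss, collapse = ", "))

  tip_state <- rep("unknown", ntip)
  idx <- match(names(states), tree$tip.label)
  tip_state[idx] <- states
  bad <- !tip_state %in% c("functional", "lost", "unknown")
  if (any(bad)) stop("invalid state: ", tip_state[bad][1])

  nnode <- ntip + tree$Nnode
  n_lost <- n_func <- integer(nnode)
  n_lost[seq_len(ntip)] <- tip_state == "lost"
  n_func[seq_len(ntip)] <- tip_state == "functional"
  lost_tips <- vector("list", nnode)
  lost_tips[seq_len(ntip)] <- lapply(seq_len(ntip), function(i) {
    if (tip_state[i] == "lost") i else integer(0)
  })
  po_edge <- if (identical(attr(tree, "order"), "postorder")) tree$edge
             else ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po_edge))) {
    p <- po_edge[i, 1L]; ch <- po_edge[i, 2L]
    n_lost[p] <- n_lost[p] + n_lost[ch]
    n_func[p] <- n_func[p] + n_func[ch]
    lost_tips[[p]] <- c(lost_tips[[p]], lost_tips[[ch]])
  }
  eligible <- n_func == 0L & n_lost >= 1L

  root <- ntip + 1L
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]

  if (eligible[root]) {
    lost <- tree$tip.label[sort(lost_tips[[root]])]
    ev <- .event_row(1L, .anchor_mrca(lost, tree), lost, flagged = TRUE)
    warning("all scored leaves are lost: a single loss at the root's child ",
            "contradicts presence at the root; event flagged")
    return(ev)
  }

  maximal <- which(eligible & !eligible[pmax(parent, 1L)] & seq_len(nnode) != root)
  if (!length(maximal)) return(.event_row())

  events <- lapply(lost_tips[maximal], function(i) tree$tip.label[i])
  ord <- order(vapply(events, function(x) sort(x)[1L], character(1)))
  events <- events[ord]
  data.frame(
    event_id = seq_along(events),
    anchor_node = vapply(events, .anchor_mrca, integer(1), tree = tree),
    leaves = vapply(events, function(x) paste(sort(x), collapse = ","), character(1)),
    n_leaves = lengths(events),
    shared_lesion = NA_character_,
    flagged = FALSE,
    stringsAsFactors = FALSE
  )
}

.norm_calls <- function(calls) {
  if (is.data.frame(calls)) {
    if (anyDuplicated(calls$species)) stop("duplicate species in calls")
    stats::setNames(calls$state, calls$species)
  } else {
    if (is.null(names(calls))) stop("'calls' must be named by species")
    if (anyDuplicated(names(calls))) stop("duplicate species in calls")
    calls
  }
}

.tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

.anchor_mrca <- function(tips, tree) {
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  as.integer(ape::getMRCA(tree, tips))
}

.event_row <- function(event_id = integer(0), anchor_node = integer(0),
                       leaves = NULL, shared_lesion = NA_character_,
                       flagged = FALSE) {
  if (!length(event_id)) {
    return(data.frame(event_id = integer(0), anchor_node = integer(0),
                      leaves = character(0), n_leaves = integer(0),
                      shared_lesion = character(0), flagged = logical(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    event_id = event_id, anchor_node = anchor_node,
    leaves = paste(sort(leaves), collapse = ","),
    n_leaves = length(leaves), shared_lesion = shared_lesion,
    flagged = flagged, stringsAsFactors = FALSE
  )
}

# do two lesion tables share at least one homologous lesion?
# Homology: same type + overlapping alignment span (+ identical ungapped
# length for indel lesions).
.share_lesion <- function(a, b) length(.shared_lesions(a, b)) > 0L

.shared_lesions <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(character(0))
  indel_types <- c("frameshift_indel", "promoter_deletion", "promoter_insertion")
  out <- character(0)
  for (i in seq_len(nrow(a))) {
    j <- which(
      b$type == a$type[i] &
        b$start <= a$end[i] & b$end >= a$start[i] &
        (!(a$type[i] %in% indel_types) | b$length_bp == a$length_bp[i])
    )
    if (length(j))
      out <- c(out, sprintf("%s@%d-%d(%dbp)", a$type[i], a$start[i], a$end[i],
                            a$length_bp[i]))
  }
  unique(out)
}

#' Split Dollo events whose supporting species carry incompatible lesions
#'
#' Within each Dollo event, two lost leaves stay in the same event only if
#' they share at least one homologous lesion: same lesion type and
#' overlapping alignment span, with identical ungapped length for indels.
#' This is the computable proxy for "the mutation events are obviously
#' independent": sister species lost through unrelated frameshifts or stops
#' are counted as separate losses, while a clade inheriting one ancestral
#' promoter rearrangement stays a single event. Leaves are grouped by
#' single-linkage over the pairwise sharing relation; each group becomes its
#' own event anchored at the stem of its leaf set.
#'
#' @param events the data frame from [dollo_events()].
#' @param reports a named list of `lesion_report`s covering the lost leaves.
#' @param tree the species tree used for `events`.
#' @return A data frame in the same layout as [dollo_events()], with
#'   `shared_lesion` filled in for multi-leaf events.
#' @export
split_by_lesion <- function(events, reports, tree) {
  if (!nrow(events)) return(events)
  out <- list()
  for (i in seq_len(nrow(events))) {
    leaves <- strsplit(events$leaves[i], ",", fixed = TRUE)[[1L]]
    have <- leaves %in% names(reports)
    if (any(!have)) {
      warning("no lesion report for: ", paste(leaves[!have], collapse = ", "),
              "; each kept as its own event")
    }
    orphans <- leaves[!have]
    leaves <- leaves[have]
    groups <- list()
    if (length(leaves) == 1L) {
      groups <- list(leaves)
    } else if (length(leaves) > 1L) {
      # single-linkage components under the lesion-sharing relation
      comp <- seq_along(leaves)
      les <- lapply(leaves, function(s) reports[[s]]$lesions)
      for (a in seq_along(leaves)) for (b in seq_len(a - 1L)) {
        if (.share_lesion(les[[a]], les[[b]])) {
          comp[comp == comp[a]] <- comp[b]
        }
      }
      groups <- split(leaves, comp)
    }
    groups <- c(groups, as.list(orphans))
    for (g in groups) {
      shared <- NA_character_
      if (length(g) > 1L) {
        common <- Reduce(
          intersect,
          lapply(g[-1L], function(s) .shared_lesions(reports[[g[1L]]]$lesions,
                                                     reports[[s]]$lesions))
        )
        if (length(common)) shared <- common[1L]
      } else if (g %in% names(reports) && nrow(reports[[g]]$lesions)) {
        l <- reports[[g]]$lesions[1L, ]
        shared <- sprintf("%s@%d-%d(%dbp)", l$type, l$start, l$end, l$length_bp)
      }
      out[[length(out) + 1L]] <- .event_row(
        0L, .anchor_mrca(g, tree), g, shared_lesion = shared,
        flagged = events$flagged[i]
      )
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$leaves), , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Count independent isoform losses on a species tree
#'
#' Runs [dollo_events()] and then [split_by_lesion()]; the number of
#' resulting events is the minimum number of independent losses consistent
#' with the tree, the calls and the observed lesions.
#'
#' @inheritParams dollo_events
#' @inheritParams split_by_lesion
#' @return A list with `count` (integer) and `events` (the event table).
#' @export
count_independent_losses <- function(tree, calls, reports) {
  ev <- dollo_events(tree, calls)
  ev <- split_by_lesion(ev, reports, tree)
  list(count = nrow(ev), events = ev)
}
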