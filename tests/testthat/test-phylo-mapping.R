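simple_states <- function(tree, lost = character(0), unknown = character(0)) {
  s <- stats::setNames(rep("functional", length(tree$tip.label)), tree$tip.label)
  s[lost] <- "lost"
  s[unknown] <- "unknown"
  s
}

test_that("basic Dollo mapping on a five-taxon tree", {
  tree <- ape::read.tree(text = "((a,b),((c,d),e));")
  expect_identical(nrow(dollo_events(tree, simple_states(tree))), 0L)

  ev <- dollo_events(tree, simple_states(tree, lost = c("c", "d")))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$leaves, "c,d")

  ev2 <- dollo_events(tree, simple_states(tree, lost = c("a", "c")))
  expect_identical(nrow(ev2), 2L)

  # unknown leaves are wildcards: a lost clade may absorb them
  ev3 <- dollo_events(tree, simple_states(tree, lost = "c", unknown = "d"))
  expect_identical(nrow(ev3), 1L)
  expect_identical(ev3$leaves, "c")
  # the anchor is the placement closest to the leaves: the tip itself
  expect_identical(ev3$anchor_node, match("c", tree$tip.label))
})

test_that("the all-lost degenerate case is a single flagged event with a warning", {
  tree <- ape::read.tree(text = "((a,b),c);")
  expect_warning(
    ev <- dollo_events(tree, simple_states(tree, lost = c("a", "b", "c"))),
    "contradicts presence at the root"
  )
  expect_identical(nrow(ev), 1L)
  expect_true(ev$flagged)
})

test_that("Dollo counts match the brute-force minimizer on all 5-leaf trees", {
  trees <- phangorn::allTrees(5, rooted = TRUE)
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    setup <- dollo_oracle_setup(tree)
    for (mask in 0:(2^5 - 2)) {
      lost_idx <- which(bitwAnd(bitwShiftL(1L, 0:4), mask) != 0L)
      states <- simple_states(tree, lost = tree$tip.label[lost_idx])
      expect_identical(nrow(dollo_events(tree, states)),
                       dollo_oracle_min(setup, lost_idx),
                       info = paste("tree", ti, "mask", mask))
    }
  }
})

test_that("the count is invariant to leaf order and ladderization", {
  tree <- ape::read.tree(text = "((a,(b,c)),((d,e),(f,g)));")
  states <- simple_states(tree, lost = c("b", "c", "d", "e"), unknown = "f")
  n0 <- nrow(dollo_events(tree, states))
  expect_identical(nrow(dollo_events(tree, states[sample(names(states))])), n0)
  expect_identical(nrow(dollo_events(ape::ladderize(tree), states)), n0)
  expect_identical(nrow(dollo_events(ape::ladderize(tree, right = FALSE), states)), n0)
})

test_that("polytomies are handled", {
  tree <- ape::read.tree(text = "((a,b,c),(d,e,f));")
  ev <- dollo_events(tree, simple_states(tree, lost = c("a", "b", "c")))
  expect_identical(nrow(ev), 1L)
  ev2 <- dollo_events(tree, simple_states(tree, lost = c("a", "d")))
  expect_identical(nrow(ev2), 2L)
})

test_that("lesion-aware splitting separates incompatible sister losses", {
  tree <- ape::read.tree(text = "((Reference,(x,y)),z);")
  tpl <- region_template()
  aln <- region_alignment(
    stats::setNames(rep(tpl$sequence, 4), c("Reference", "x", "y", "z")),
    tpl$annotation
  )
  # x and y: different frameshifts; z stays functional
  planted <- plant_lesions(aln, tree, list(
    lesion_spec("x", "frameshift_indel", start = 640, length_bp = 2),
    lesion_spec("y", "frameshift_indel", start = 610, length_bp = 1)
  ))
  reports <- build_feature_reports(planted$alignment, include_reference = FALSE)
  calls <- call_all(reports)
  ev <- dollo_events(tree, calls)
  expect_identical(nrow(ev), 1L) # x,y form one lost clade
  split <- split_by_lesion(ev, reports, tree)
  expect_identical(nrow(split), 2L)

  # identical inherited lesion: stays one event
  planted2 <- plant_lesions(aln, tree, list(
    lesion_spec(c("x", "y"), "frameshift_indel", start = 640, length_bp = 2)
  ))
  reports2 <- build_feature_reports(planted2$alignment, include_reference = FALSE)
  ev2 <- dollo_events(tree, call_all(reports2))
  split2 <- split_by_lesion(ev2, reports2, tree)
  expect_identical(nrow(split2), 1L)
  expect_match(split2$shared_lesion, "frameshift_indel")
})

test_that("splitting never decreases the event count", {
  set.seed(7)
  for (i in 1:25) {
    sc <- simulate_loss_scenario(n_taxa = 10, n_events = sample(1:5, 1), seed = i)
    reports <- build_feature_reports(sc$alignment, include_reference = FALSE)
    calls <- call_all(reports)
    ev <- dollo_events(sc$tree, calls)
    split <- split_by_lesion(ev, reports, sc$tree)
    expect_gte(nrow(split), nrow(ev))
  }
})

test_that("a lost leaf without a report is kept as its own event, with a warning", {
  tree <- ape::read.tree(text = "((Reference,(x,y)),z);")
  tpl <- region_template()
  aln <- region_alignment(
    stats::setNames(rep(tpl$sequence, 4), c("Reference", "x", "y", "z")),
    tpl$annotation
  )
  planted <- plant_lesions(aln, tree, list(
    lesion_spec(c("x", "y"), "donor_loss")
  ))
  reports <- build_feature_reports(planted$alignment, include_reference = FALSE)
  calls <- call_all(reports)
  ev <- dollo_events(tree, calls)
  expect_warning(
    split <- split_by_lesion(ev, reports[!names(reports) %in% "y"], tree),
    "no lesion report"
  )
  expect_identical(nrow(split), 2L)
})
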