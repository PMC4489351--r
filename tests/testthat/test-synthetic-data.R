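test_that("simulate_tree is reproducible and has the right shape", {
  t1 <- simulate_tree(24, seed = 7)
  t2 <- simulate_tree(24, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(length(t1$tip.label), 24L)
  expect_identical(t1$Nnode, 23L)

  cherry <- simulate_tree(2, seed = 1)
  expect_identical(length(cherry$tip.label), 2L)
  expect_error(simulate_tree(1), ">= 2")

  expect_false(identical(ape::write.tree(simulate_tree(24, seed = 8)),
                         ape::write.tree(t1)))
})

test_that("neutral evolution preserves columns and protected positions", {
  tpl <- region_template()
  tree <- simulate_tree(6, seed = 3)

  frozen <- evolve_region(tpl, tree, sub_rate = 0, seed = 1)
  for (sp in names(frozen$seqs)) expect_identical(frozen$seqs[[sp]], tpl$sequence)

  hot <- evolve_region(tpl, tree, sub_rate = 0.8, seed = 2)
  ref <- strsplit(tpl$sequence, "")[[1]]
  for (sp in tree$tip.label) {
    row <- strsplit(hot$seqs[[sp]], "")[[1]]
    expect_identical(length(row), length(ref))
    expect_false(any(row == "-"))
    expect_identical(row[tpl$protected_cols], ref[tpl$protected_cols], info = sp)
  }
  # high-rate rows do diverge outside the protected set
  expect_gt(sum(strsplit(hot$seqs[[tree$tip.label[1]]], "")[[1]] != ref), 50)

  # lesion detectors stay silent on background divergence
  reports <- build_feature_reports(hot, include_reference = FALSE)
  expect_true(all(call_all(reports)$state == "functional"))
})

test_that("per-row substitution counts track the Poisson expectation", {
  tpl <- region_template()
  # single long branch: one cherry with unit branch lengths
  tree <- ape::read.tree(text = "(a:1,b:1);")
  rate <- 0.05
  ref <- strsplit(tpl$sequence, "")[[1]]
  free <- setdiff(seq_along(ref), tpl$protected_cols)
  nsub <- vapply(1:60, function(s) {
    aln <- evolve_region(tpl, tree, sub_rate = rate, seed = s)
    sum(strsplit(aln$seqs[["a"]], "")[[1]] != ref)
  }, numeric(1))
  expected <- length(free) * (1 - exp(-rate))
  # binomial mean with n=60 replicates: allow 4 sigma
  sigma <- sqrt(length(free) * (1 - exp(-rate)) / 60)
  expect_lt(abs(mean(nsub) - expected), 4 * sigma + 1)
})

test_that("plant_lesions applies clade-inherited lesions with an exact truth table", {
  tpl <- region_template()
  tree <- ape::read.tree(text = "((m1,(m2,(m3,(m4,m5)))),(o1,o2));")
  aln <- region_alignment(
    stats::setNames(rep(tpl$sequence, 8),
                    c("Reference", paste0("m", 1:5), "o1", "o2")),
    tpl$annotation
  )
  muroid <- paste0("m", 1:5)
  planted <- plant_lesions(aln, tree, list(
    lesion_spec(muroid, "promoter_deletion", start = 441, length_bp = 80),
    lesion_spec(muroid, "promoter_insertion", start = 480)
  ))
  truth <- planted$truth
  expect_identical(truth$expected_events, 1L)
  states <- stats::setNames(truth$leaf_states$state, truth$leaf_states$species)
  expect_true(all(states[muroid] == "lost"))
  expect_true(all(states[c("o1", "o2")] == "functional"))

  # and the pipeline agrees
  reports <- build_feature_reports(planted$alignment, include_reference = FALSE)
  calls <- call_all(reports)
  expect_identical(stats::setNames(calls$state, calls$species)[names(states)], states)
  res <- count_independent_losses(tree, calls, reports)
  expect_identical(res$count, 1L)

  # two distinct frameshifts on sister leaves: two events
  planted2 <- plant_lesions(aln, tree, list(
    lesion_spec("o1", "frameshift_indel", start = 640, length_bp = 2),
    lesion_spec("o2", "frameshift_indel", start = 610, length_bp = 1)
  ))
  expect_identical(planted2$truth$expected_events, 2L)

  # empty spec list: everyone functional, zero events
  planted3 <- plant_lesions(aln, tree, list())
  expect_true(all(planted3$truth$leaf_states$state == "functional"))
  expect_identical(planted3$truth$expected_events, 0L)

  # contradictory overlapping specs are rejected
  expect_error(
    plant_lesions(aln, tree, list(
      lesion_spec("o1", "premature_stop", start = 573),
      lesion_spec(c("o1", "o2"), "premature_stop", start = 573, seq = "TAA")
    )),
    "contradictory"
  )
})

test_that("a start-codon-only lesion is not loss-causing unless both are hit", {
  tpl <- region_template()
  tree <- ape::read.tree(text = "(a,(b,c));")
  aln <- region_alignment(
    stats::setNames(rep(tpl$sequence, 4), c("Reference", "a", "b", "c")),
    tpl$annotation
  )
  one <- plant_lesions(aln, tree, list(lesion_spec("b", "start1_loss")))
  expect_identical(one$truth$leaf_states$state[one$truth$leaf_states$species == "b"],
                   "functional")
  expect_identical(one$truth$expected_events, 0L)

  both <- plant_lesions(aln, tree, list(
    lesion_spec("b", "start1_loss"), lesion_spec("b", "start2_loss")
  ))
  expect_identical(both$truth$leaf_states$state[both$truth$leaf_states$species == "b"],
                   "lost")
  expect_identical(both$truth$expected_events, 1L)
})

test_that("count simulation hits its expectations and reproduces under a seed", {
  expect_equal(expected_counts(1, 473),
               c(exon_1A = 228, exon_1B = 245, exon_6 = 426))
  expect_equal(unname(expected_counts(Inf, 1000)[1]), 0)
  expect_equal(unname(expected_counts(0, 1000)[2]), 0)
  expect_error(expected_counts(-1, 100), ">= 0")

  c1 <- simulate_counts(8, 2000, seed = 5)
  c2 <- simulate_counts(8, 2000, seed = 5)
  expect_identical(c1, c2)
  expect_identical(simulate_counts(Inf, 500, seed = 2)$exon_1A, 0L)

  # long-run mean of the null draw matches the expectation
  set.seed(1)
  sims <- vapply(1:300, function(s) {
    unlist(simulate_counts(1, 473, seed = s)[, c("exon_1A", "exon_1B", "exon_6")])
  }, numeric(3))
  expect_lt(max(abs(rowMeans(sims) - expected_counts(1, 473))), 4)
})

test_that("the packaged worked-example fixture matches its documented truth", {
  fix <- make_fixture_fig2a()
  expect_identical(sort(fix$tree$tip.label),
                   sort(names(fix$alignment$seqs)))
  expect_identical(names(fix$alignment$seqs)[1], "Homo")

  reports <- build_feature_reports(fix$alignment)
  calls <- call_all(reports)
  states <- stats::setNames(calls$state, calls$species)
  expect_identical(unname(states[c("Homo", "Macaca", "Bos", "Cavia", "Macropus")]),
                   rep("functional", 5))
  expect_identical(unname(states[c("Mus", "Rattus", "Meriones", "Ctenomys",
                                   "Octodon", "Echinops", "Erinaceus", "Sus",
                                   "Sorex")]),
                   rep("lost", 9))
  expect_identical(unname(states[c("Muroid_sp1", "Muroid_sp2")]),
                   rep("unknown", 2))

  # the one-ATG species initiate at ATG2
  site <- stats::setNames(calls$initiation_site, calls$species)
  expect_identical(unname(site[c("Equus", "Vicugna")]), c(2L, 2L))
  expect_identical(unname(site[["Homo"]]), 1L)

  # the muroid promoter insertion is the documented 72-bp event
  ins <- reports[["Mus"]]$lesions
  expect_true(any(ins$type == "promoter_insertion" & ins$length_bp == 72))
})
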