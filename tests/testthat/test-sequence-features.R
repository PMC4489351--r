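# columns used below are fixed by region_template(): ATG1 at 561, ATG2 at
# 591, coding block 561-650, donor at 651, TSS block 441-520

test_that("the reference row against itself yields no lesions and two strong ATGs", {
  aln <- mutated_alignment()
  rep <- build_feature_report(aln, "Reference")
  expect_identical(nrow(rep$lesions), 0L)
  expect_true(rep$start_codons[[1]]$intact)
  expect_true(rep$start_codons[[2]]$intact)
  expect_identical(rep$start_codons[[1]]$kozak_class, "strong")
  expect_identical(rep$start_codons[[2]]$kozak_class, "strong")
  expect_identical(rep$promoter_status, "intact")
  expect_true(rep$donor_intact)
  # determinism: a second run is identical
  expect_identical(rep, build_feature_report(aln, "Reference"))
})

test_that("start-codon scan reports mutated, gapped and ambiguous codons", {
  # ATG1 mutated to ACG, ATG2 untouched (the one-ATG species archetype)
  aln <- mutated_alignment(subs = list(list(562, "C")))
  st <- scan_start_codons(aln, "mut")
  expect_false(st[[1]]$intact)
  expect_identical(st[[1]]$observed_codon, "ACG")
  expect_true(st[[2]]$intact)

  # both mutated
  aln2 <- mutated_alignment(subs = list(list(562, "C"), list(592, "C")))
  st2 <- scan_start_codons(aln2, "mut")
  expect_false(st2[[1]]$intact)
  expect_false(st2[[2]]$intact)

  # codon inside an alignment gap
  aln3 <- mutated_alignment(dels = list(c(561, 3)))
  st3 <- scan_start_codons(aln3, "mut")
  expect_identical(st3[[1]]$observed_codon, "---")
  expect_false(st3[[1]]$intact)

  # N makes the status unknown rather than lost
  aln4 <- mutated_alignment(subs = list(list(561, "N")))
  st4 <- scan_start_codons(aln4, "mut")
  expect_true(is.na(st4[[1]]$intact))
})

test_that("frameshift parity: 1-2 bp indels are flagged, 3 bp are not", {
  for (len in 1:6) {
    aln <- mutated_alignment(dels = list(c(600, len)))
    les <- detect_orf_disruptions(aln, "mut")
    fs <- les[les$type == "frameshift_indel", ]
    if (len %% 3 == 0) {
      expect_identical(nrow(fs), 0L, info = paste("deletion length", len))
    } else {
      expect_identical(nrow(fs), 1L, info = paste("deletion length", len))
      expect_identical(fs$length_bp, len)
    }
  }
})

test_that("insertions relative to the reference also shift the frame", {
  # splice two inserted columns into the coding block: reference gains gaps,
  # the mutated row gains bases
  tpl <- region_template()
  ref <- strsplit(tpl$sequence, "")[[1]]
  row <- ref
  at <- 600
  ref2 <- c(ref[1:at], c("-", "-"), ref[(at + 1):length(ref)])
  row2 <- c(row[1:at], c("C", "A"), row[(at + 1):length(row)])
  ann <- feature_annotation(
    promoter_block = c(1, 440), tss_block = c(441, 520),
    atg1_pos = 561, atg2_pos = 591, coding_block = c(561, 652), donor_pos = 653
  )
  aln <- region_alignment(
    c(Reference = paste(ref2, collapse = ""), mut = paste(row2, collapse = "")),
    ann
  )
  les <- detect_orf_disruptions(aln, "mut")
  expect_true(any(les$type == "frameshift_indel" & les$length_bp == 2))
})

test_that("premature stops are found in the ATG1-anchored frame, shifted by indels", {
  # direct in-frame TAG (codon 5 of the template: columns 573-575)
  aln <- mutated_alignment(subs = list(list(573, "T"), list(574, "A"), list(575, "G")))
  les <- detect_orf_disruptions(aln, "mut")
  expect_identical(les$type, "premature_stop")
  expect_identical(reported_stop_codons(aln, "mut"), oracle_stop_codons(aln, "mut"))

  # a 2-bp deletion followed by a TGA readable only in the shifted frame:
  # delete columns 567-568; codon 3 of the row then starts at column 569
  aln2 <- mutated_alignment(
    dels = list(c(567, 2)),
    subs = list(list(569, "T"), list(570, "G"), list(571, "A"))
  )
  les2 <- detect_orf_disruptions(aln2, "mut")
  expect_setequal(les2$type, c("frameshift_indel", "premature_stop"))
  expect_identical(reported_stop_codons(aln2, "mut"), oracle_stop_codons(aln2, "mut"))

  # the same TGA bases without the deletion are out of frame: no stop
  aln3 <- mutated_alignment(
    subs = list(list(569, "T"), list(570, "G"), list(571, "A"))
  )
  expect_identical(oracle_stop_codons(aln3, "mut"), integer(0))
  expect_identical(reported_stop_codons(aln3, "mut"), integer(0))
})

test_that("premature-stop calls match the translation oracle on random mutated rows", {
  set.seed(42)
  for (i in 1:200) {
    n_sub <- sample(0:8, 1)
    subs <- lapply(sample(561:650, n_sub), function(col) {
      list(col, sample(c("A", "C", "G", "T"), 1))
    })
    dels <- NULL
    if (runif(1) < 0.5) {
      at <- sample(565:640, 1)
      dels <- list(c(at, sample(1:4, 1)))
    }
    aln <- mutated_alignment(subs = subs, dels = dels)
    expect_identical(reported_stop_codons(aln, "mut"), oracle_stop_codons(aln, "mut"),
                     info = paste("random row", i))
  }
})

test_that("only the canonical GT donor passes; gaps and N handled", {
  bases <- c("A", "C", "G", "T")
  for (b1 in bases) for (b2 in bases) {
    aln <- mutated_alignment(subs = list(list(651, b1), list(652, b2)))
    donor <- check_splice_donor(aln, "mut")
    expect_identical(donor$intact, b1 == "G" && b2 == "T",
                     info = paste0("donor ", b1, b2))
  }
  gapped <- mutated_alignment(dels = list(c(651, 2)))
  donor <- check_splice_donor(gapped, "mut")
  expect_false(donor$intact)
  expect_match(donor$lesions$detail, "donor deleted")

  nn <- mutated_alignment(subs = list(list(651, "N")))
  expect_true(is.na(check_splice_donor(nn, "mut")$intact))
})

test_that("promoter assessment: intact, rearranged and absent verdicts", {
  expect_identical(assess_promoter(mutated_alignment(), "mut")$status, "intact")

  # deletion over the TSS block
  del <- mutated_alignment(dels = list(c(460, 40)))
  pr <- assess_promoter(del, "mut")
  expect_identical(pr$status, "rearranged")
  expect_true(any(pr$lesions$type == "promoter_deletion" & pr$lesions$length_bp == 40))

  # same-size deletion confined to the far upstream promoter block does not
  # rearrange the TSS
  up <- mutated_alignment(dels = list(c(50, 40)))
  expect_identical(assess_promoter(up, "mut")$status, "intact")

  # short indels are alignment noise
  short <- mutated_alignment(dels = list(c(460, 10)))
  expect_identical(assess_promoter(short, "mut")$status, "intact")

  # >= 90% of the promoter block gapped
  gone <- mutated_alignment(dels = list(c(1, 430)))
  expect_identical(assess_promoter(gone, "mut")$status, "absent")
})

test_that("the muroid-style rearrangement reports a 72-bp insertion", {
  tree <- ape::read.tree(text = "(Reference,(m1,m2));")
  tpl <- region_template()
  aln <- region_alignment(
    stats::setNames(rep(tpl$sequence, 3), c("Reference", "m1", "m2")),
    tpl$annotation
  )
  planted <- plant_lesions(aln, tree, list(
    lesion_spec(c("m1", "m2"), "promoter_deletion", start = 441, length_bp = 80),
    lesion_spec(c("m1", "m2"), "promoter_insertion", start = 480)
  ))
  pr <- assess_promoter(planted$alignment, "m1")
  expect_identical(pr$status, "rearranged")
  ins <- pr$lesions[pr$lesions$type == "promoter_insertion", ]
  expect_identical(nrow(ins), 1L)
  expect_identical(ins$length_bp, 72L)
})

test_that("enlarging a TSS-overlapping deletion never reverts a rearranged call", {
  statuses <- vapply(seq(30, 80, by = 10), function(len) {
    assess_promoter(mutated_alignment(dels = list(c(490, len))), "mut")$status
  }, character(1))
  expect_true(all(statuses == "rearranged"))
})

test_that("the aggregate report equals the union of the individual detectors", {
  aln <- mutated_alignment(
    subs = list(list(562, "C"), list(652, "C"),
                list(582, "T"), list(583, "A"), list(584, "A")),
    dels = list(c(460, 35))
  )
  rep <- build_feature_report(aln, "mut")
  manual <- rbind(
    assess_promoter(aln, "mut")$lesions,
    check_splice_donor(aln, "mut")$lesions,
    detect_orf_disruptions(aln, "mut")
  )
  # start1_loss lesion is added for the mutated ATG1
  expect_setequal(
    rep$lesions$type,
    c(manual$type, "start1_loss")
  )
  expect_identical(sum(rep$lesions$type == "donor_loss"), 1L)
  expect_identical(sum(rep$lesions$type == "premature_stop"), 1L)
})

test_that("a fully gapped row collapses to a single region_absent lesion", {
  tpl <- region_template()
  aln <- region_alignment(
    c(Reference = tpl$sequence, gone = strrep("-", nchar(tpl$sequence))),
    tpl$annotation
  )
  rep <- build_feature_report(aln, "gone")
  expect_identical(rep$lesions$type, "region_absent")
  expect_true(rep$region_absent)
  expect_identical(rep$promoter_status, "absent")
})
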