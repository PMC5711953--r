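test_that("marker matrices parse symbols, round-trip, and reject bad input", {
  calls <- matrix(c("+", "-", "?", "1", "0", "NA"), nrow = 3,
                  dimnames = list(c("A", "B", "C"), c("l1", "l2")))
  m <- marker_matrix(calls)
  expect_equal(unname(m$calls[, "l2"]), c("+", "-", "?"))
  expect_equal(sum(m$calls == "?"), 2)

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_marker_matrix(m, tf)
  m2 <- read_marker_matrix(tf)
  expect_identical(m$calls, m2$calls)

  bad <- calls; bad[1, 1] <- "maybe"
  expect_error(marker_matrix(bad), "unknown state symbol 'maybe'")
  expect_error(marker_matrix(calls[, c(1, 1)]), "duplicate locus")
  dup <- calls; rownames(dup) <- c("A", "A", "C")
  expect_error(marker_matrix(dup), "duplicate taxon")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("taxon", empty)
  expect_error(read_marker_matrix(empty), "empty")
})

test_that("polarization assigns the documented statuses on a toy tree", {
  # tree (((A,B),C),(D,E)); A is the reference
  mat <- toy_matrix(list(
    all_present = list(pres = c("A", "B", "C", "D", "E")),
    autapomorphy = list(pres = "A"),
    clean_ab = list(pres = c("A", "B")),
    shallow_outgroup = list(pres = c("A", "B", "C")),
    conflict = list(pres = c("A", "C")),
    missing_ok = list(pres = c("A", "B"), miss = "C")
  ))
  tree <- toy_tree()
  expect_equal(polarize_marker(mat, tree, "all_present")$status,
               "UNINFORMATIVE")
  expect_equal(polarize_marker(mat, tree, "autapomorphy")$status,
               "UNINFORMATIVE")
  cl <- polarize_marker(mat, tree, "clean_ab")
  expect_equal(cl$status, "CLEAN")
  expect_equal(cl$branch, c("A", "B"))
  expect_false(cl$depends_on_missing)
  # (A,B,C) stem has only the (D,E) pair below it: one lineage < 2
  expect_equal(polarize_marker(mat, tree, "shallow_outgroup")$status,
               "INSUFFICIENT_OUTGROUP")
  expect_equal(polarize_marker(mat, tree, "shallow_outgroup",
                               stringency = 1)$status, "CLEAN")
  am <- polarize_marker(mat, tree, "conflict")
  expect_equal(am$status, "AMBIGUOUS")
  expect_equal(am$conflict, "B")
  # missing C is compatible with both the (A,B) and (A,B,C) branches:
  # the shallower branch wins, the dependence is flagged, and only one
  # deeper lineage can confirm absence
  mm <- polarize_marker(mat, tree, "missing_ok")
  expect_equal(mm$status, "INSUFFICIENT_OUTGROUP")
  expect_equal(mm$branch, c("A", "B"))
  expect_true(mm$depends_on_missing)
  expect_equal(polarize_marker(mat, tree, "missing_ok",
                               stringency = 1)$status, "CLEAN")
  expect_error(polarize_marker(mat, tree, "nope"), "not in matrix")
  expect_error(polarize_markers(mat, ape::read.tree(text = "((A,B),C);")),
               "absent from the tree")
  expect_error(polarize_markers(mat, ape::unroot(toy_tree())), "rooted")
})

test_that("every locus gets exactly one status and order does not matter", {
  set.seed(42)
  fx <- macropus_fixture()
  pol <- polarize_markers(fx$matrix, fx$tree)
  st <- vapply(pol$results, `[[`, "", "status")
  expect_length(st, 29)
  expect_true(all(st %in% c("CLEAN", "AMBIGUOUS", "UNINFORMATIVE",
                            "INSUFFICIENT_OUTGROUP")))

  perm_t <- sample(length(fx$matrix$taxa))
  perm_l <- sample(length(fx$matrix$loci))
  shuffled <- marker_matrix(fx$matrix$calls[perm_t, perm_l])
  pol2 <- polarize_markers(shuffled, fx$tree)
  st2 <- vapply(pol2$results, `[[`, "", "status")
  expect_identical(st[names(st2)], st2)
  for (l in fx$matrix$loci)
    expect_identical(pol$results[[l]]$branch, pol2$results[[l]]$branch)
})

test_that("the fixture reproduces the published marker inventory", {
  fx <- macropus_fixture()
  pol <- polarize_markers(fx$matrix, fx$tree)
  st <- vapply(pol$results, `[[`, "", "status")
  expect_length(st, 29)                     # 29 informative loci
  expect_equal(sum(st == "AMBIGUOUS"), 8)   # conflicts C1-C8
  expect_equal(sort(names(st)[st == "AMBIGUOUS"]), paste0("C", 1:8))
  # deepest markers have a single observable outgroup lineage
  expect_equal(unname(st[c("K16", "K17", "K18", "K19")]),
               rep("INSUFFICIENT_OUTGROUP", 4))
})

test_that("trifurcation counting reproduces every published node pattern", {
  fx <- macropus_fixture()
  pol <- polarize_markers(fx$matrix, fx$tree)
  expected <- list(i = c(2, 1), ii = c(6, 1), iii = c(8, 0),
                   iv = c(9, 1), v = c(3, 1), vi = c(3, 0),
                   vii = c(1, 0), viii = c(4, 0))
  for (nm in names(expected)) {
    cnt <- count_trifurcation(pol, fx$nodes[[nm]]$spec)
    expect_equal(c(cnt$t1, cnt$t2), expected[[nm]], label = paste("node", nm))
    expect_true(is.na(cnt$t3))
  }
  # the conflicting loci behind the headline counts
  cnt_ii <- count_trifurcation(pol, fx$nodes$ii$spec)
  expect_equal(attr(cnt_ii, "support_loci")$t2, "C3")
  amb <- count_trifurcation(pol, fx$nodes$ii$spec, include_ambiguous = TRUE)
  expect_equal(c(amb$t1, amb$t2), c(11, 2))
  expect_setequal(attr(amb, "ambiguous_loci")$t1,
                  c("C1", "C5", "C6", "C7", "C8"))
  expect_equal(attr(amb, "ambiguous_loci")$t2, "C2")
})

test_that("trifurcation counting validates its inputs", {
  fx <- macropus_fixture()
  pol <- polarize_markers(fx$matrix, fx$tree)
  expect_error(trifurcation("A", c("A", "B"), "C", "A"), "disjoint")
  expect_error(trifurcation("A", "B", "C", "Z"), "exactly one clade")
  bad <- trifurcation("Macropus_irma", "NotATaxon", "Wallabia_bicolor",
                      "NotATaxon")
  expect_error(count_trifurcation(pol, bad), "not in the matrix")
})

test_that("ratio counts recover the published successive-branch patterns", {
  fx <- macropus_fixture()
  pol <- polarize_markers(fx$matrix, fx$tree)
  rc_ii <- ratio_count_for_clade(pol, fx$nodes$ii$ratio_clade, fx$reference)
  expect_equal(c(rc_ii$shared, rc_ii$exclusive), c(6, 2))
  rc_iii <- ratio_count_for_clade(pol, fx$nodes$iii$ratio_clade,
                                  fx$reference,
                                  within = fx$nodes$iii$ratio_within)
  expect_equal(c(rc_iii$shared, rc_iii$exclusive), c(8, 0))
  rc_iv <- ratio_count_for_clade(pol, fx$nodes$iv$ratio_clade,
                                 fx$reference,
                                 within = fx$nodes$iv$ratio_within)
  expect_equal(c(rc_iv$shared, rc_iv$exclusive), c(9, 2))
  rc_viii <- ratio_count_for_clade(pol, fx$nodes$viii$ratio_clade,
                                   fx$reference)
  expect_equal(c(rc_viii$shared, rc_viii$exclusive), c(4, 0))
  expect_false(attr(rc_ii, "untestable"))

  expect_error(ratio_count_for_clade(pol, c("Wallabia_bicolor",
                                            "Macropus_irma"),
                                     fx$reference), "reference")
  expect_error(
    ratio_count_for_clade(pol, c("Macropus_eugenii", "Wallabia_bicolor"),
                          fx$reference),
    "not a reference-path clade")
})

test_that("an empty tally is flagged untestable, not an error", {
  mat <- toy_matrix(list(only_deep = list(pres = c("A", "B", "C"))))
  pol <- polarize_markers(mat, toy_tree(), stringency = 1)
  rc <- ratio_count_for_clade(pol, c("A", "B"), "A")
  expect_equal(c(rc$shared, rc$exclusive), c(0, 0))
  expect_true(attr(rc, "untestable"))
  spec <- trifurcation("B", "A", "C", "A")
  cnt <- count_trifurcation(pol, spec)
  expect_equal(c(cnt$t1, cnt$t2), c(0, 0))
  expect_error(kksc_onedir(cnt), "at least one")
})
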