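test_that("planted proteome: exact group recovery, determinism, empty plant", {
  sim <- simulateProteome(100, plantedRepeats = list(
    list(residue = "Q", nMembers = 10, runLength = 6)), seed = 11)
  px <- buildPolyXGroups(sim$proteome, 4)
  expect_setequal(groupMembers(px, "Q"), sim$truth$groups$Q)
  # suppression: no accidental runs of any residue anywhere
  reps <- repeatTable(px)
  expect_equal(nrow(reps), 10)
  expect_true(all(reps$residue == "Q"))
  # planted coordinates are re-derivable by scanning
  m <- merge(reps, sim$truth$runs, by = c("protein_id", "residue"))
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$end.x, m$end.y)

  # same seed -> identical bytes
  sim2 <- simulateProteome(100, plantedRepeats = list(
    list(residue = "Q", nMembers = 10, runLength = 6)), seed = 11)
  expect_identical(as.character(sim$proteome), as.character(sim2$proteome))

  none <- simulateProteome(50, plantedRepeats = list(), seed = 3)
  expect_equal(sum(groupSizes(buildPolyXGroups(none$proteome, 4))), 0L)

  expect_error(simulateProteome(10, plantedRepeats = list(
    list(residue = "Q", nMembers = 2, runLength = 100)),
    lengthRange = c(150, 160)), "too short")
})

test_that("unsuppressed proteomes get a post-hoc scanned ground truth", {
  sim <- simulateProteome(60, plantedRepeats = list(
    list(residue = "Q", nMembers = 6, runLength = 6)),
    suppressAccidentalRuns = FALSE, seed = 13)
  px <- buildPolyXGroups(sim$proteome, 4)
  for (x in names(sim$truth$groups))
    expect_setequal(groupMembers(px, x), sim$truth$groups[[x]])
})

test_that("planted-partition interactome: realized counts and null behaviour", {
  universe <- sprintf("P%04d", 1:500)
  group <- universe[1:50]
  inter <- simulateInteractome(list(group), pIn = 0.2, pOut = 0.01,
                               universe, seed = 17)
  # realized within-group edges within 4 SD of C(50,2) * 0.2 = 245
  gn <- extractGroupNetwork(inter, group)
  expW <- choose(50, 2) * 0.2
  sdW <- sqrt(choose(50, 2) * 0.2 * 0.8)
  expect_lt(abs(nrow(typeA(gn)) - expW), 4 * sdW)
  expect_equal(nrow(typeA(gn)), attr(inter, "withinEdges"))

  expect_identical(
    edgeTable(simulateInteractome(list(group), 0.2, 0.01, universe, seed = 17)),
    edgeTable(inter))

  # depletion fixture: fewer within-group edges than background rate implies
  dep <- simulateInteractome(list(group), pIn = 0.004, pOut = 0.01,
                             universe, seed = 19)
  expect_lt(nrow(typeA(extractGroupNetwork(dep, group))),
            choose(50, 2) * 0.01)
})

test_that("domain annotations honor qIn/qOut and planted overlap placement", {
  set.seed(23)
  universe <- sprintf("P%04d", 1:300)
  sim <- simulateProteome(300, plantedRepeats = list(
    list(residue = "Q", nMembers = 100, runLength = 6)), seed = 29)
  grp <- sim$truth$groups$Q
  for (w in c(0, 1)) {
    ann <- simulateDomainAnnotations(
      sim$truth$groups, universe,
      planted = list(list(domainId = "DOM", residue = "Q", qIn = 1,
                          qOut = 0, overlapRate = w, length = 30)),
      runsTruth = sim$truth$runs, seqLengths = sim$truth$lengths,
      seed = 31 + w)
    expect_setequal(unique(ann$protein_id[ann$domain_id == "DOM"]), grp)
    sm <- overlapSummary("Q", "DOM", sim$truth$runs, ann, 4)
    expect_equal(sm$fraction, w)
  }
})

test_that("a written study round-trips through the readers with zero warnings", {
  dir <- file.path(tempdir(), "simstudy")
  res <- simulateStudy(dir, nProteins = 120,
                       plantedRepeats = list(list(residue = "Q",
                                                  nMembers = 15,
                                                  runLength = 6)),
                       nDecoys = 3, seed = 37)
  expect_true(all(file.exists(unlist(res$paths))))
  expect_no_warning({
    prot <- readProteome(res$paths$proteome)
    inter <- readInteractions(res$paths$interactome)
    ann <- readDomainAnnotations(res$paths$domains)
  })
  # ground truth is re-derivable from the emitted files alone
  px <- buildPolyXGroups(prot, 4)
  expect_setequal(groupMembers(px, "Q"), res$truth$groups$Q)
  gn <- extractGroupNetwork(inter, res$truth$groups$Q)
  expect_equal(nrow(typeA(gn)), res$truth$realized_within_edges)
  expect_setequal(unique(ann$protein_id[ann$domain_id == "DOM_COIL"]),
                  res$truth$domain_carriers$DOM_COIL)
})
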