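writeFasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

test_that("FASTA reading: records, wrapped sequences, header extraction", {
  aa <- readProteome(writeFasta(c(">P1", "MQA", ">P2", "KK")))
  expect_equal(names(aa), c("P1", "P2"))
  expect_equal(as.character(aa), c(P1 = "MQA", P2 = "KK"))

  aa <- readProteome(writeFasta(c(">P1 desc here", "AAA", "QQQ")))
  expect_equal(as.character(aa), c(P1 = "AAAQQQ"))

  aa <- readProteome(writeFasta(c(">sp|P12345|NAME_HUMAN desc", "MAAA")),
                     idExtractor = "uniprot")
  expect_equal(names(aa), "P12345")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(readProteome(empty), 0)
})

test_that("FASTA reading rejects duplicate ids and empty records", {
  expect_error(readProteome(writeFasta(c(">P1", "MQA", ">P1", "KK"))),
               "duplicate")
  expect_error(readProteome(writeFasta(c(">P1", "", ">P2", "KK"))),
               "empty sequence")
  expect_error(readProteome(tempfile()), "not found")
})

test_that("homopolymer runs: thresholds, maximality, non-standard letters", {
  expect_equal(findHomopolymerRuns("AAAA", 4),
               data.frame(residue = "A", start = 1L, end = 4L, length = 4L,
                          stringsAsFactors = FALSE))
  expect_equal(nrow(findHomopolymerRuns("AAA", 4)), 0)
  r <- findHomopolymerRuns("MQQQQQAPPPPL", 4)
  expect_equal(r$residue, c("Q", "P"))
  expect_equal(r$start, c(2L, 8L))
  expect_equal(r$end, c(6L, 11L))
  # a single maximal run, no sub-runs
  expect_equal(nrow(findHomopolymerRuns("QQQQQQ", 4)), 1)
  expect_equal(findHomopolymerRuns("QQQQQQ", 4)$length, 6L)
  # non-standard letters are never run residues and break runs
  expect_equal(nrow(findHomopolymerRuns("XXXXXX", 2)), 0)
  expect_equal(nrow(findHomopolymerRuns("QQXQQ", 4)), 0)
  expect_equal(nrow(findHomopolymerRuns("", 4)), 0)
})

test_that("scanner matches the brute-force per-substring oracle", {
  set.seed(101)
  for (i in 1:100) {
    s <- randomSequence(sample(200, 1), alphabet = c("A", "Q", "L", "X"))
    got <- findHomopolymerRuns(s, 3)
    want <- oracleRuns(s, 3)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = s)
  }
})

test_that("scanner run lengths are bounded by residue counts and shrink monotonically", {
  set.seed(202)
  for (i in 1:25) {
    s <- randomSequence(150, alphabet = c("A", "Q", "P"))
    runs <- findHomopolymerRuns(s, 2)
    ch <- strsplit(s, "")[[1]]
    for (x in unique(runs$residue))
      expect_lte(sum(runs$length[runs$residue == x]), sum(ch == x))
    prev <- findHomopolymerRuns(s, 2)$residue
    for (m in 3:6) {
      cur <- findHomopolymerRuns(s, m)$residue
      expect_true(all(table(cur) <= table(factor(prev, levels = unique(c(prev, cur))))[names(table(cur))]))
      prev <- cur
    }
  }
})

test_that("polyX groups: membership, degenerate threshold, singleton proteome", {
  prot <- c(P1 = "MQQQQA", P2 = "AAAAQQ", P3 = "MLLLLL")
  px <- buildPolyXGroups(prot, 4)
  expect_equal(groupMembers(px, "Q"), "P1")
  expect_equal(groupMembers(px, "A"), "P2")
  expect_equal(groupMembers(px, "L"), "P3")
  expect_equal(sum(groupSizes(px)), 3L)

  px1 <- buildPolyXGroups(prot, 1)
  for (p in names(prot)) {
    letters <- unique(strsplit(prot[[p]], "")[[1]])
    for (x in letters)
      expect_true(p %in% groupMembers(px1, x))
  }

  pk <- buildPolyXGroups(c(PK = "KKKK"), 4)
  expect_equal(groupMembers(pk, "K"), "PK")
  expect_equal(sum(groupSizes(pk)), 1L)
  expect_error(buildPolyXGroups(character(0)), "empty")
})

test_that("raising the run-length threshold never adds a group member", {
  set.seed(303)
  prot <- setNames(replicate(30, randomSequence(120,
                                                alphabet = c("A", "Q", "S"))),
                   sprintf("P%02d", 1:30))
  prev <- buildPolyXGroups(prot, 2)
  for (m in 3:6) {
    cur <- buildPolyXGroups(prot, m)
    for (x in AA_STANDARD)
      expect_true(all(groupMembers(cur, x) %in% groupMembers(prev, x)))
    prev <- cur
  }
})

test_that("repeat and group TSV artifacts are well-formed", {
  px <- buildPolyXGroups(c(P1 = "MQQQQA", P2 = "AAAAQQ"), 4)
  f1 <- tempfile(); f2 <- tempfile()
  writeRepeatsTsv(px, f1)
  writeGroupsTsv(px, f2)
  reps <- read.delim(f1)
  expect_equal(names(reps), c("protein_id", "residue", "start", "end", "length"))
  grp <- read.delim(f2)
  expect_equal(nrow(grp), 20)
  expect_equal(grp$n_proteins[grp$residue == "Q"], 1L)
})
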