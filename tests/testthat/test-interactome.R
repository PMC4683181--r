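writeEdges <- function(rows) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(rows, tf)
  tf
}

test_that("interaction reading collapses duplicates, orientation and self-loops", {
  inter <- readInteractions(writeEdges(c("P1\tP2", "P2\tP1", "P1\tP1")))
  expect_equal(edgeCount(inter), 1)
  expect_equal(sort(nodeIds(inter)), c("P1", "P2"))

  inter <- readInteractions(writeEdges(c("A\tB", "B\tC")))
  expect_equal(edgeCount(inter), 2)
  expect_equal(sort(nodeIds(inter)), c("A", "B", "C"))

  expect_error(readInteractions(writeEdges(character(0))), "zero edges")
  expect_error(readInteractions(writeEdges(c("P1\tP1"))), "zero edges")
})

test_that("self-interactions can be retained and count as one type-a edge", {
  inter <- readInteractions(writeEdges(c("A\tB", "A\tA")),
                            keepSelfLoops = TRUE)
  gn <- extractGroupNetwork(inter, c("A", "B"))
  expect_equal(nrow(typeA(gn)), 2)   # A-B plus the A-A loop
  deg <- withinGroupDegrees(gn)
  expect_equal(deg[["A"]], 2L)       # loop counted with multiplicity 1
  expect_equal(deg[["B"]], 1L)
})

test_that("BioGRID-style files are read through their symbol columns", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c(paste("#ID A", "#ID B", "Official Symbol Interactor A",
                     "Official Symbol Interactor B", sep = "\t"),
               paste("1", "2", "TP53", "MDM2", sep = "\t"),
               paste("3", "4", "MDM2", "TP53", sep = "\t")), tf)
  # the header row starts with '#': read with comment disabled by format
  raw <- read.delim(tf, check.names = FALSE)
  expect_true("Official Symbol Interactor A" %in% names(raw))
  inter <- readInteractions(tf, format = "biogrid_tab",
                            colA = "Official Symbol Interactor A",
                            colB = "Official Symbol Interactor B")
  expect_equal(edgeCount(inter), 1)
  expect_equal(sort(nodeIds(inter)), c("MDM2", "TP53"))
  expect_error(readInteractions(tf, format = "biogrid_tab",
                                colA = "No Such Column"),
               "lacks columns")
})

test_that("group network classification matches the two-type definition", {
  gn <- extractGroupNetwork(toyInteractome(), c("A", "B", "C"))
  expect_equal(nrow(typeA(gn)), 1)
  expect_equal(sort(paste(typeA(gn)[, 1], typeA(gn)[, 2])), "A B")
  expect_equal(nrow(typeB(gn)), 3)
  # X-Y (two non-members) is not retained anywhere
  expect_false(any(apply(rbind(typeA(gn), typeB(gn)), 1,
                         function(e) setequal(e, c("X", "Y")))))
  expect_equal(sort(presentMembers(gn)), c("A", "B", "C"))

  # group = all nodes: everything is type a
  allg <- extractGroupNetwork(toyInteractome(),
                              nodeIds(toyInteractome()))
  expect_equal(nrow(typeA(allg)), edgeCount(toyInteractome()))
  expect_equal(nrow(typeB(allg)), 0)

  # disjoint group: empty classified sets
  none <- extractGroupNetwork(toyInteractome(), c("Z1", "Z2"))
  expect_equal(nrow(typeA(none)), 0)
  expect_equal(nrow(typeB(none)), 0)
  expect_length(presentMembers(none), 0)
})

test_that("within-group degrees satisfy the handshake identity", {
  gn <- extractGroupNetwork(toyInteractome(), c("A", "B", "C"))
  deg <- withinGroupDegrees(gn)
  expect_equal(deg, c(A = 1L, B = 1L, C = 0L))
  expect_equal(sum(deg), 2 * nrow(typeA(gn)))

  tri <- extractGroupNetwork(
    makeInteractome(data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"))),
    c("A", "B", "C"))
  expect_equal(unname(withinGroupDegrees(tri)), c(2L, 2L, 2L))
  expect_equal(sum(withinGroupDegrees(tri)), 6)
})

test_that("classified counts match brute-force recounts on random graphs", {
  set.seed(404)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    ids <- sprintf("N%02d", seq_len(n))
    pairs <- t(combn(ids, 2))
    sel <- runif(nrow(pairs)) < 0.15
    if (!any(sel)) next
    df <- data.frame(a = pairs[sel, 1], b = pairs[sel, 2])
    # randomize orientation in the input
    flip <- runif(nrow(df)) < 0.5
    df[flip, ] <- df[flip, c(2, 1)]
    inter <- makeInteractome(df)
    group <- sample(ids, sample(2:n, 1))
    gn <- extractGroupNetwork(inter, group)
    want <- oracleClassify(data.frame(pairs[sel, 1], pairs[sel, 2]), group)
    expect_equal(nrow(typeA(gn)), want$type_a)
    expect_equal(nrow(typeB(gn)), want$type_b)
    expect_equal(nrow(typeA(gn)) + nrow(typeB(gn)), want$incident)
  }
})
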