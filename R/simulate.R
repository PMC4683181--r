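# Synthetic-data generator: proteomes with planted homopolymer runs,
# planted-partition interactomes, and domain annotations with planted
# group-level enrichment and planted positional overlap with runs.

#' Default background amino-acid composition
#'
#' Approximate residue frequencies of a vertebrate proteome, used as the
#' i.i.d. background when simulating sequences.
#'
#' @return named numeric vector over [AA_STANDARD], summing to 1.
#' @export
defaultComposition <- function() {
  f <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.4, V = 6.0, W = 1.2, Y = 2.7)
  f[AA_STANDARD] / sum(f)
}

# Resample, in `chars`, the positions of accidental runs (>= minRunLength)
# that are not exactly a planted interval, leaving planted positions
# untouched.  `planted` is a data.frame with residue/start/end.
suppressRuns <- function(chars, planted, minRunLength, composition) {
  plantedPos <- if (nrow(planted))
    unlist(mapply(seq, planted$start, planted$end, SIMPLIFY = FALSE))
  else integer()
  key <- if (nrow(planted))
    paste(planted$residue, planted$start, planted$end) else character()
  for (iter in 1:200) {
    runs <- findHomopolymerRuns(paste(chars, collapse = ""), minRunLength)
    bad <- runs[!(paste(runs$residue, runs$start, runs$end) %in% key), ,
                drop = FALSE]
    if (!nrow(bad)) return(chars)
    for (i in seq_len(nrow(bad))) {
      pos <- setdiff(seq(bad$start[i], bad$end[i]), plantedPos)
      chars[pos] <- sample(AA_STANDARD, length(pos), replace = TRUE,
                           prob = composition)
    }
  }
  stop("accidental-run suppression did not converge")
}

#' Simulate a proteome with planted homopolymer runs
#'
#' Background residues are drawn i.i.d. from `composition`; accidental
#' runs at or above `minRunLength` are suppressed by resampling the
#' offending window (so planted group membership is exact), unless
#' `suppressAccidentalRuns = FALSE`, in which case the ground truth is
#' recomputed post hoc by scanning the emitted sequences.
#'
#' @param nProteins number of proteins (ids `P0001`, ...).
#' @param plantedRepeats list of specs, each a list with `residue`,
#'   `nMembers` (or `fraction` of the proteome) and `runLength` (scalar or
#'   `c(min, max)` sampled uniformly per protein).
#' @param lengthRange `c(min, max)` sequence length, sampled uniformly.
#' @param composition background residue frequencies (default
#'   [defaultComposition()]).
#' @param minRunLength run-length threshold the suppression and the
#'   post-hoc scan use (default 4).
#' @param suppressAccidentalRuns suppress background runs (default TRUE).
#' @param plantMargin minimum distance of a planted run from either
#'   sequence end, reserving room for a disjoint domain placement
#'   (default 49).
#' @param seed RNG seed; identical seeds give identical output.
#' @return list with `proteome` (named [Biostrings::AAStringSet]) and
#'   `truth`: `groups` (residue -> member ids), `runs` (planted or scanned
#'   run table), `lengths`, `minRunLength`, `seed`.
#' @export
simulateProteome <- function(nProteins,
                             plantedRepeats = list(),
                             lengthRange = c(150L, 300L),
                             composition = defaultComposition(),
                             minRunLength = 4L,
                             suppressAccidentalRuns = TRUE,
                             plantMargin = 49L,
                             seed = 1L) {
  stopifnot(nProteins >= 1, lengthRange[1] <= lengthRange[2])
  maxRun <- max(c(4L, unlist(lapply(plantedRepeats, `[[`, "runLength"))))
  if (lengthRange[1] < maxRun + 2 * plantMargin)
    stop("sequences too short for the planted runs and margin")
  ids <- sprintf("P%04d", seq_len(nProteins))
  withSeed(seed, {
    lens <- sample(seq(lengthRange[1], lengthRange[2]), nProteins,
                   replace = TRUE)
    seqChars <- lapply(lens, function(L)
      sample(AA_STANDARD, L, replace = TRUE, prob = composition))
    names(seqChars) <- names(lens) <- ids
    groups <- list(); runRows <- list()
    for (spec in plantedRepeats) {
      res <- spec$residue
      stopifnot(res %in% AA_STANDARD)
      nm <- if (!is.null(spec$nMembers)) spec$nMembers
            else round(spec$fraction * nProteins)
      members <- sample(ids, nm)
      groups[[res]] <- members
      for (p in members) {
        L <- lens[[p]]
        rl <- if (length(spec$runLength) == 2)
          sample(seq(spec$runLength[1], spec$runLength[2]), 1)
        else spec$runLength
        # avoid previously planted intervals on this protein
        prev <- do.call(rbind, runRows[names(runRows) == p])
        ok <- FALSE
        for (try in 1:50) {
          s <- sample(seq(plantMargin + 1, L - rl - plantMargin + 1), 1)
          e <- s + rl - 1
          if (is.null(prev) ||
              all(intervalOverlapLength(s - 2, e + 2, prev$start,
                                        prev$end) == 0)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place planted run in ", p)
        seqChars[[p]][s:e] <- res
        # flanks must differ from the run residue (maximality)
        for (fl in c(s - 1, e + 1)) {
          if (fl >= 1 && fl <= L && seqChars[[p]][fl] == res)
            seqChars[[p]][fl] <- sample(setdiff(AA_STANDARD, res), 1)
        }
        runRows[[length(runRows) + 1]] <- data.frame(
          protein_id = p, residue = res, start = s, end = e,
          length = rl, stringsAsFactors = FALSE)
        names(runRows)[length(runRows)] <- p
      }
    }
    runs <- if (length(runRows)) do.call(rbind, runRows) else
      data.frame(protein_id = character(), residue = character(),
                 start = integer(), end = integer(), length = integer(),
                 stringsAsFactors = FALSE)
    rownames(runs) <- NULL
    if (suppressAccidentalRuns) {
      for (p in ids) {
        pl <- runs[runs$protein_id == p, , drop = FALSE]
        seqChars[[p]] <- suppressRuns(seqChars[[p]], pl, minRunLength,
                                      composition)
      }
    }
    seqs <- vapply(seqChars, paste, character(1), collapse = "")
    proteome <- Biostrings::AAStringSet(seqs)
    names(proteome) <- ids
    if (!suppressAccidentalRuns) {
      runs <- scanRepeats(seqs, minRunLength)
      groups <- lapply(AA_STANDARD, function(x)
        unique(runs$protein_id[runs$residue == x]))
      names(groups) <- AA_STANDARD
      groups <- groups[vapply(groups, length, integer(1)) > 0]
    }
    list(proteome = proteome,
         truth = list(groups = groups, runs = runs, lengths = lens,
                      minRunLength = as.integer(minRunLength), seed = seed))
  })
}

#' Simulate a planted-partition interactome
#'
#' Every unordered pair within a planted group receives an edge with
#' probability `pIn`; every other pair with probability `pOut`.  `pIn <
#' pOut` is allowed (anti-connected, depletion-style fixtures).
#'
#' @param groups list of planted member-id vectors (may be empty).
#' @param pIn,pOut within-group and background edge probabilities.
#' @param universe all protein ids (nodes are drawn from these).
#' @param seed RNG seed.
#' @return an [Interactome]; attributes `withinEdges` / `outsideEdges`
#'   give the realized counts.
#' @export
simulateInteractome <- function(groups, pIn, pOut, universe, seed = 1L) {
  n <- length(universe)
  stopifnot(n >= 2, pIn >= 0, pIn <= 1, pOut >= 0, pOut <= 1)
  totalPairs <- n * (n - 1) / 2
  withSeed(seed, {
    withinKeys <- unique(unlist(lapply(groups, function(g) {
      idx <- match(unique(g), universe)
      if (anyNA(idx)) stop("group member outside universe")
      if (length(idx) < 2) return(numeric())
      cmb <- combn(idx, 2)
      pairIndexEncode(cmb[1, ], cmb[2, ])
    })))
    withinSel <- withinKeys[runif(length(withinKeys)) < pIn]
    nOutPairs <- totalPairs - length(withinKeys)
    mOut <- rbinom(1, nOutPairs, pOut)
    outSel <- numeric()
    if (mOut > 0) {
      draw <- sample(totalPairs, min(totalPairs,
                                     mOut + length(withinKeys) + 100L))
      outSel <- setdiff(draw, withinKeys)[seq_len(mOut)]
    }
    keys <- c(withinSel, outSel)
    if (!length(keys)) stop("simulated interactome has zero edges")
    ij <- pairIndexDecode(keys)
    inter <- makeInteractome(data.frame(a = universe[ij[, 1]],
                                        b = universe[ij[, 2]],
                                        stringsAsFactors = FALSE))
    attr(inter, "withinEdges") <- length(withinSel)
    attr(inter, "outsideEdges") <- length(outSel)
    inter
  })
}

# place a domain instance of length dLen relative to a planted run [s, e]
# on a protein of length len: overlapping (>= 4 shared residues) or
# disjoint (zero shared residues with every run in `allRuns`).
placeDomain <- function(len, s, e, dLen, overlap) {
  if (overlap) {
    dStart <- if (s + dLen - 1 <= len) s else max(1, e - dLen + 1)
    c(dStart, min(len, dStart + dLen - 1))
  } else {
    if (s - 1 >= dLen + 1) {
      dStart <- sample(seq_len(s - dLen - 1), 1)
    } else if (len - e >= dLen + 1) {
      dStart <- e + 1 + sample(seq_len(len - e - dLen), 1)
    } else stop("protein too short to place a disjoint domain")
    c(dStart, dStart + dLen - 1)
  }
}

#' Simulate domain annotations with planted enrichment and overlap
#'
#' Each planted domain is assigned to members of its target group with
#' probability `qIn` and to every other protein with probability `qOut`.
#' When coordinates are requested (`seqLengths` supplied), a planted
#' instance on a protein that carries a planted run of the target residue
#' is positioned to overlap that run by at least 4 residues with
#' probability `overlapRate`, and strictly away from it otherwise; decoy
#' domains are assigned uniformly at random positions.
#'
#' @param groups named list of planted group member ids (names are
#'   residues).
#' @param universe all protein ids.
#' @param planted list of specs: `domainId`, `residue`, `qIn`, `qOut`,
#'   optional `overlapRate` (default 0) and `length` (default 30).
#' @param nDecoys number of decoy domains (`DECOY_01`, ...).
#' @param decoyRate per-protein carriage probability of each decoy.
#' @param decoyLength decoy instance length (default 20).
#' @param runsTruth planted-run table (from [simulateProteome()]) used for
#'   overlap placement; required when `overlapRate` > 0.
#' @param seqLengths named protein lengths; `NULL` emits coordinate-free
#'   annotations.
#' @param seed RNG seed.
#' @return annotation data.frame (protein_id, domain_id, start, end) with
#'   attribute `truth` (planted domain ids and carrier lists).
#' @export
simulateDomainAnnotations <- function(groups, universe, planted = list(),
                                      nDecoys = 0L, decoyRate = 0.05,
                                      decoyLength = 20L, runsTruth = NULL,
                                      seqLengths = NULL, seed = 1L) {
  withSeed(seed, {
    rows <- list(); truth <- list(planted = character(), carriers = list())
    for (spec in planted) {
      stopifnot(!is.null(spec$domainId), !is.null(spec$qIn),
                !is.null(spec$qOut))
      members <- if (!is.null(spec$residue)) groups[[spec$residue]]
                 else spec$members
      w <- if (is.null(spec$overlapRate)) 0 else spec$overlapRate
      dLen <- if (is.null(spec$length)) 30L else spec$length
      others <- setdiff(universe, members)
      carriers <- c(members[runif(length(members)) < spec$qIn],
                    others[runif(length(others)) < spec$qOut])
      truth$planted <- c(truth$planted, spec$domainId)
      truth$carriers[[spec$domainId]] <- carriers
      for (p in carriers) {
        if (is.null(seqLengths)) {
          rows[[length(rows) + 1]] <- data.frame(
            protein_id = p, domain_id = spec$domainId,
            start = NA_integer_, end = NA_integer_,
            stringsAsFactors = FALSE)
          next
        }
        len <- seqLengths[[p]]
        run <- if (!is.null(runsTruth) && !is.null(spec$residue))
          runsTruth[runsTruth$protein_id == p &
                    runsTruth$residue == spec$residue, , drop = FALSE]
        else NULL
        if (!is.null(run) && nrow(run)) {
          se <- placeDomain(len, run$start[1], run$end[1], dLen,
                            overlap = runif(1) < w)
        } else {
          dStart <- sample(len - dLen + 1, 1)
          se <- c(dStart, dStart + dLen - 1)
        }
        rows[[length(rows) + 1]] <- data.frame(
          protein_id = p, domain_id = spec$domainId,
          start = as.integer(se[1]), end = as.integer(se[2]),
          stringsAsFactors = FALSE)
      }
    }
    for (d in seq_len(nDecoys)) {
      did <- sprintf("DECOY_%02d", d)
      carriers <- universe[runif(length(universe)) < decoyRate]
      for (p in carriers) {
        if (is.null(seqLengths)) {
          se <- c(NA_integer_, NA_integer_)
        } else {
          dStart <- sample(seqLengths[[p]] - decoyLength + 1, 1)
          se <- c(dStart, dStart + decoyLength - 1L)
        }
        rows[[length(rows) + 1]] <- data.frame(
          protein_id = p, domain_id = did,
          start = as.integer(se[1]), end = as.integer(se[2]),
          stringsAsFactors = FALSE)
      }
    }
    ann <- if (length(rows)) do.call(rbind, rows) else
      data.frame(protein_id = character(), domain_id = character(),
                 start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    rownames(ann) <- NULL
    attr(ann, "truth") <- truth
    ann
  })
}

#' Generate a complete synthetic study and write it to disk
#'
#' Emits `proteome.fasta`, `interactome.tsv` (two-column edge list),
#' `domains.tsv` and `truth.json` in `outDir`.  The defaults emulate a
#' polyQ-like study condition: 400 proteins, one planted group of 40
#' polyQ proteins (runs of 6), a planted-partition interactome with a
#' 2.4-fold elevated within-group edge probability, and one planted domain
#' enriched in the group with a 50 percent repeat-overlap rate, plus
#' decoy domains.
#'
#' @param outDir output directory (created if needed).
#' @param nProteins,lengthRange,plantedRepeats see [simulateProteome()].
#' @param pIn,pOut see [simulateInteractome()].
#' @param plantedDomains,nDecoys,decoyRate see
#'   [simulateDomainAnnotations()].
#' @param seed master seed; every stage derives its sub-seed from it.
#' @return invisible list with `paths` and `truth`.
#' @export
simulateStudy <- function(outDir,
                          nProteins = 400L,
                          lengthRange = c(150L, 300L),
                          plantedRepeats = list(
                            list(residue = "Q", nMembers = 40L,
                                 runLength = 6L)),
                          pIn = 0.024, pOut = 0.01,
                          plantedDomains = list(
                            list(domainId = "DOM_COIL", residue = "Q",
                                 qIn = 0.5, qOut = 0.05,
                                 overlapRate = 0.5, length = 30L)),
                          nDecoys = 10L, decoyRate = 0.05,
                          seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateProteome(nProteins, plantedRepeats, lengthRange,
                          seed = deriveSeed(seed, 101))
  universe <- names(sim$proteome)
  inter <- simulateInteractome(sim$truth$groups, pIn, pOut, universe,
                               seed = deriveSeed(seed, 102))
  ann <- simulateDomainAnnotations(sim$truth$groups, universe,
                                   planted = plantedDomains,
                                   nDecoys = nDecoys, decoyRate = decoyRate,
                                   runsTruth = sim$truth$runs,
                                   seqLengths = sim$truth$lengths,
                                   seed = deriveSeed(seed, 103))
  paths <- list(proteome = file.path(outDir, "proteome.fasta"),
                interactome = file.path(outDir, "interactome.tsv"),
                domains = file.path(outDir, "domains.tsv"),
                truth = file.path(outDir, "truth.json"))
  Biostrings::writeXStringSet(sim$proteome, paths$proteome)
  writeTsv(edgeTable(inter), paths$interactome)
  writeTsv(ann, paths$domains)
  truth <- list(
    seed = seed,
    groups = sim$truth$groups,
    planted_runs = sim$truth$runs,
    p_in = pIn, p_out = pOut,
    realized_within_edges = attr(inter, "withinEdges"),
    realized_outside_edges = attr(inter, "outsideEdges"),
    planted_domains = attr(ann, "truth")$planted,
    domain_carriers = attr(ann, "truth")$carriers,
    overlap_rates = setNames(
      vapply(plantedDomains,
             function(s) if (is.null(s$overlapRate)) 0 else s$overlapRate,
             numeric(1)),
      vapply(plantedDomains, `[[`, character(1), "domainId")))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}
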