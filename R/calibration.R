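# Simulation studies: null calibration of the control-normalized
# connectivity indexes, planted-effect recovery, enrichment recovery and
# overlap recovery.  These run the same pipeline functions as a real
# analysis (simulateInteractome -> groupConnectivity -> ...) over many
# replicates with derived sub-seeds.

#' Null calibration of the connectivity analysis
#'
#' Simulates datasets in which the "group" is itself a random draw and the
#' interactome is exchangeable (`pIn = pOut`), then runs the full
#' group-vs-controls connectivity computation on each.  Under this null
#' the mean normalized ratios should be close to 1 and the chi-squared
#' step should reject near its nominal level.
#'
#' The rejection rate is reported for both chi-squared constructions: the
#' "pooled" construction (summed control counts) is correctly calibrated,
#' while the "mean" construction (rounded average counts) treats the
#' 5-control average as if it were a single sample and is therefore
#' conservative.
#'
#' @param nSim number of simulated datasets.
#' @param universeSize,groupSize proteome size and group size.
#' @param edgeProb shared edge probability (`pIn = pOut`).
#' @param nControls control replicates per dataset (default 5).
#' @param alpha chi-squared significance level.
#' @param seed master seed.
#' @return list: `meanNormProportion`, `meanNormPerNode` (grand means of
#'   the per-dataset mean ratios), `chi2RejectionRatePooled`,
#'   `chi2RejectionRateMean`, `nSim`.
#' @export
nullConnectivityCalibration <- function(nSim = 1000L, universeSize = 500L,
                                        groupSize = 40L, edgeProb = 0.05,
                                        nControls = 5L, alpha = 0.05,
                                        seed = 1L) {
  universe <- sprintf("P%04d", seq_len(universeSize))
  prop <- pn <- numeric(nSim)
  rejPooled <- rejMean <- logical(nSim)
  for (s in seq_len(nSim)) {
    sub <- deriveSeed(seed, 1L, s)
    group <- withSeed(deriveSeed(sub, 7L), sample(universe, groupSize))
    inter <- simulateInteractome(list(), edgeProb, edgeProb, universe,
                                 seed = deriveSeed(sub, 8L))
    res <- groupConnectivity(inter, group, universe, nControls,
                             seed = sub, tag = "null",
                             chi2Controls = "pooled")
    prop[s] <- res$norm_proportion$mean
    pn[s] <- res$norm_per_node$mean
    rejPooled[s] <- !is.na(res$chi2_p) && res$chi2_p < alpha
    chiMean <- yatesChi2Test(res$type_a, res$type_b,
                             round(mean(res$control_type_a)),
                             round(mean(res$control_type_b)))
    rejMean[s] <- !is.na(chiMean$p.value) && chiMean$p.value < alpha
  }
  list(meanNormProportion = mean(prop), meanNormPerNode = mean(pn),
       chi2RejectionRatePooled = mean(rejPooled),
       chi2RejectionRateMean = mean(rejMean), nSim = nSim)
}

#' Planted-effect recovery of the per-node connectivity index
#'
#' Simulates planted-partition interactomes with `pIn = rho * pOut` and
#' measures the control-normalized indexes of the planted group.  With the
#' group small relative to the universe, the mean normalized per-node
#' index estimates `rho` (up to the small upward bias of a ratio of
#' counts).
#'
#' @param nSim number of replicates.
#' @param universeSize,groupSize proteome and planted group size.
#' @param pOut background edge probability.
#' @param rho within/background edge-probability ratio (`pIn = rho *
#'   pOut`); values below 1 give depletion fixtures.
#' @param nControls control replicates per dataset.
#' @param seed master seed.
#' @return list: `meanNormPerNode`, `meanNormProportion`, `rho`, `nSim`.
#' @export
plantedEffectRecovery <- function(nSim = 200L, universeSize = 600L,
                                  groupSize = 60L, pOut = 0.01, rho = 2.4,
                                  nControls = 5L, seed = 1L) {
  universe <- sprintf("P%04d", seq_len(universeSize))
  prop <- pn <- numeric(nSim)
  for (s in seq_len(nSim)) {
    sub <- deriveSeed(seed, 2L, s)
    group <- withSeed(deriveSeed(sub, 7L), sample(universe, groupSize))
    inter <- simulateInteractome(list(group), rho * pOut, pOut, universe,
                                 seed = deriveSeed(sub, 8L))
    res <- groupConnectivity(inter, group, universe, nControls,
                             seed = sub, tag = "planted")
    prop[s] <- res$norm_proportion$mean
    pn[s] <- res$norm_per_node$mean
  }
  list(meanNormPerNode = mean(pn), meanNormProportion = mean(prop),
       rho = rho, nSim = nSim)
}

#' Recovery of a planted enriched domain
#'
#' Replicated draws of domain annotations with one planted domain
#' (`qIn` in the group, `qOut` outside) plus decoy domains assigned
#' uniformly, each analyzed with the per-group hypergeometric/BH test.
#'
#' @param nSim replicates.
#' @param backgroundSize,groupSize background and group sizes.
#' @param qIn,qOut planted carriage probabilities.
#' @param nDecoys,decoyRate decoy domains and their uniform carriage rate.
#' @param alpha BH-adjusted significance threshold.
#' @param seed master seed.
#' @return list: `detectionRate` (replicates where the planted domain is
#'   significant), `decoyReplicateRate` (replicates with at least one
#'   significant decoy), `nSim`.
#' @export
enrichmentRecovery <- function(nSim = 100L, backgroundSize = 400L,
                               groupSize = 40L, qIn = 0.5, qOut = 0.05,
                               nDecoys = 50L, decoyRate = 0.05,
                               alpha = 0.05, seed = 1L) {
  universe <- sprintf("P%04d", seq_len(backgroundSize))
  detected <- decoyHit <- logical(nSim)
  for (s in seq_len(nSim)) {
    sub <- deriveSeed(seed, 3L, s)
    group <- withSeed(deriveSeed(sub, 7L), sample(universe, groupSize))
    ann <- simulateDomainAnnotations(
      list(Q = group), universe,
      planted = list(list(domainId = "DOM_PLANT", residue = "Q",
                          qIn = qIn, qOut = qOut)),
      nDecoys = nDecoys, decoyRate = decoyRate,
      seed = deriveSeed(sub, 8L))
    tab <- hypergeomEnrichment(group, ann, universe, alpha = alpha)
    planted <- tab[tab$domain_id == "DOM_PLANT", , drop = FALSE]
    detected[s] <- nrow(planted) == 1 && planted$significant
    decoys <- tab[grepl("^DECOY_", tab$domain_id), , drop = FALSE]
    decoyHit[s] <- any(decoys$significant)
  }
  list(detectionRate = mean(detected), decoyReplicateRate = mean(decoyHit),
       nSim = nSim)
}

#' Recovery of a planted repeat/domain overlap rate
#'
#' Simulates a proteome with one planted polyX group, assigns a planted
#' domain to every group member with instances positioned to overlap the
#' planted run with probability `w`, rescans the emitted sequences, and
#' measures the overlap fraction through [overlapSummary()].
#'
#' @param w planted overlap rate in [0, 1].
#' @param nProteins proteome size.
#' @param groupSize planted group size (= number of co-occurring
#'   proteins, since `qIn = 1`).
#' @param runLength planted run length.
#' @param minOverlap overlap threshold (default 4).
#' @param seed master seed.
#' @return list: `fraction` (estimated), `w` (planted), `nTotal`.
#' @export
overlapRecovery <- function(w, nProteins = 300L, groupSize = 150L,
                            runLength = 6L, minOverlap = 4L, seed = 1L) {
  sim <- simulateProteome(nProteins,
                          plantedRepeats = list(
                            list(residue = "Q", nMembers = groupSize,
                                 runLength = runLength)),
                          seed = deriveSeed(seed, 4L))
  ann <- simulateDomainAnnotations(
    sim$truth$groups, names(sim$proteome),
    planted = list(list(domainId = "DOM_OV", residue = "Q",
                        qIn = 1, qOut = 0, overlapRate = w, length = 30L)),
    runsTruth = sim$truth$runs, seqLengths = sim$truth$lengths,
    seed = deriveSeed(seed, 5L))
  reps <- scanRepeats(sim$proteome, sim$truth$minRunLength)
  sm <- overlapSummary("Q", "DOM_OV", reps, ann, minOverlap)
  list(fraction = sm$fraction, w = w, nTotal = sm$n_total)
}
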