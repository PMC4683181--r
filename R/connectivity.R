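#' Sample equinumerous random control groups
#'
#' Draws `nControls` independent sets of `size` distinct protein ids from
#' the sampling universe (by default the full proteome).  Each replicate's
#' draw is seeded deterministically from `(seed, tag, replicate)`, so
#' results are reproducible and replicates/groups are independent.
#'
#' @param universe character vector of candidate ids.
#' @param size group size (<= length(universe)).
#' @param nControls number of control replicates (default 5).
#' @param seed master seed.
#' @param tag group label (e.g. the residue letter) mixed into the
#'   per-replicate sub-seed.
#' @return list of `nControls` character vectors.
#' @export
sampleControlGroups <- function(universe, size, nControls = 5L, seed = 1L,
                                tag = "") {
  stopifnot(nControls >= 1)
  if (size > length(universe))
    stop("control group size (", size, ") exceeds universe (",
         length(universe), ")")
  lapply(seq_len(nControls), function(i)
    withSeed(deriveSeed(seed, tagCode(tag), i),
             sample(universe, size)))
}

#' Type-a proportion index of a group network
#'
#' The number of within-group (type a) interactions as a proportion of all
#' interactions of the group's network: |a| / (|a| + |b|).
#'
#' @param gn a [GroupNetwork].
#' @return numeric in [0, 1]; `NA` with a message when the network has no
#'   interactions at all.
#' @export
proportionIndex <- function(gn) {
  a <- nrow(typeA(gn)); b <- nrow(typeB(gn))
  if (a + b == 0) {
    return(structure(NA_real_, reason = "no interactions"))
  }
  a / (a + b)
}

#' Per-node type-a interaction index of a group network
#'
#' Twice the number of type-a edges divided by the size of the denominator
#' node set: the mean within-group degree.
#'
#' @param gn a [GroupNetwork].
#' @param denominator `"present_members"` (members with at least one
#'   interaction of any type; the default), `"typea_nodes"` (members with a
#'   type-a interaction) or `"all_members"`.
#' @return numeric >= 0; `NA` (with reason) when the denominator set is
#'   empty.
#' @export
perNodeIndex <- function(gn,
                         denominator = c("present_members", "typea_nodes",
                                         "all_members")) {
  denominator <- match.arg(denominator)
  a <- typeA(gn)
  nA <- nrow(a)
  denomSet <- switch(denominator,
    present_members = presentMembers(gn),
    typea_nodes = unique(c(a[, 1], a[, 2])),
    all_members = groupMembers(gn))
  if (length(denomSet) == 0)
    return(structure(NA_real_, reason = "empty denominator set"))
  2 * nA / length(denomSet)
}

#' Normalize a raw index against control values
#'
#' @param raw the group's raw index value.
#' @param controls numeric vector of the same index on the control
#'   replicates; all must be > 0.
#' @return list with `ratios` (raw / control, per replicate), `mean` and
#'   `sem` (sample SD / sqrt(n)).
#' @examples
#' normalizeAgainstControls(0.5, rep(0.25, 5))$mean  # 2
#' @export
normalizeAgainstControls <- function(raw, controls) {
  stopifnot(length(controls) >= 1)
  if (any(is.na(controls)) || any(controls <= 0))
    stop("control index values must be positive; resample upstream")
  ratios <- raw / controls
  list(ratios = ratios, mean = mean(ratios), sem = sampleSem(ratios))
}

# One control replicate's (type a, type b, proportion, per-node) with the
# resampling policy: replicates whose indexes are undefined or whose
# type-a count is zero are redrawn with a fresh sub-seed, up to 100 times.
controlReplicate <- function(interactome, universe, size, seed, tag, rep,
                             denominator) {
  for (attempt in 0:99) {
    sub <- deriveSeed(seed, tagCode(tag), rep + 1000L * attempt)
    members <- withSeed(sub, sample(universe, size))
    gn <- extractGroupNetwork(interactome, members)
    nA <- nrow(typeA(gn)); nB <- nrow(typeB(gn))
    prop <- proportionIndex(gn)
    pn <- perNodeIndex(gn, denominator)
    if (!is.na(prop) && !is.na(pn) && nA > 0) {
      if (attempt > 0)
        message("control replicate ", rep, " of group ", tag,
                " resampled ", attempt, " time(s)")
      return(list(members = members, type_a = nA, type_b = nB,
                  proportion = prop, per_node = pn))
    }
  }
  stop("control replicate for group ", tag,
       " still degenerate after 100 resampling attempts")
}

#' Connectivity analysis of one protein group against random controls
#'
#' Computes the two connectivity indexes for the group's network, the same
#' indexes on `nControls` equinumerous random control networks, the
#' control-normalized ratios (mean +/- SEM), and the Yates chi-squared test
#' of the group's type-a/type-b split against the control counts.
#'
#' @param interactome an [Interactome].
#' @param members the group's protein ids.
#' @param universe sampling universe for the controls (default: all
#'   proteome ids if `polyx` given, else the interactome nodes).
#' @param nControls number of control replicates (default 5).
#' @param seed master seed.
#' @param tag group label used in seeding and messages.
#' @param chi2Controls `"mean"`: compare against the rounded mean control
#'   counts; `"pooled"`: against the summed control counts.
#' @param denominator passed to [perNodeIndex()].
#' @return list: raw counts/indexes, per-replicate control table, ratio
#'   vectors with means and SEMs, chi-squared statistic and p-value.
#' @export
groupConnectivity <- function(interactome, members, universe,
                              nControls = 5L, seed = 1L, tag = "",
                              chi2Controls = c("mean", "pooled"),
                              denominator = "present_members") {
  chi2Controls <- match.arg(chi2Controls)
  gn <- extractGroupNetwork(interactome, members)
  nA <- nrow(typeA(gn)); nB <- nrow(typeB(gn))
  rawProp <- proportionIndex(gn)
  rawPn <- perNodeIndex(gn, denominator)
  if (is.na(rawProp) || is.na(rawPn))
    return(structure(list(skipped = TRUE,
                          reason = "group indexes undefined (no interactions)"),
                     class = "polyXnetSkipped"))
  ctrl <- lapply(seq_len(nControls), function(i)
    controlReplicate(interactome, universe, length(unique(members)),
                     seed, tag, i, denominator))
  ctrlA <- vapply(ctrl, `[[`, numeric(1), "type_a")
  ctrlB <- vapply(ctrl, `[[`, numeric(1), "type_b")
  ctrlProp <- vapply(ctrl, `[[`, numeric(1), "proportion")
  ctrlPn <- vapply(ctrl, `[[`, numeric(1), "per_node")
  normProp <- normalizeAgainstControls(rawProp, ctrlProp)
  normPn <- normalizeAgainstControls(rawPn, ctrlPn)
  cmp <- if (chi2Controls == "mean") c(round(mean(ctrlA)), round(mean(ctrlB)))
         else c(sum(ctrlA), sum(ctrlB))
  chi <- yatesChi2Test(nA, nB, cmp[1], cmp[2])
  list(network = gn, n_members = length(unique(members)),
       n_present = length(presentMembers(gn)),
       type_a = nA, type_b = nB,
       raw_proportion = as.numeric(rawProp), raw_per_node = as.numeric(rawPn),
       control_type_a = ctrlA, control_type_b = ctrlB,
       control_proportions = ctrlProp, control_per_node = ctrlPn,
       norm_proportion = normProp, norm_per_node = normPn,
       chi2_stat = chi$statistic, chi2_p = chi$p.value)
}

#' Connectivity analysis of every polyX group
#'
#' Runs [groupConnectivity()] for every group of size >= `minGroupSize`,
#' then the cross-group statistical battery: one-way ANOVA over the
#' per-group normalized per-node ratios, Dunnett many-to-one comparisons
#' against the group whose mean ratio is closest to 1, and the Pearson
#' correlation between the two mean normalized indexes across groups.
#'
#' @param polyx a [PolyXGroups] object, or a named list of id vectors.
#' @param interactome an [Interactome].
#' @param universe control sampling universe; default: all proteome ids
#'   (when `polyx` is a [PolyXGroups]) else the interactome nodes.
#' @param nControls,seed,chi2Controls,denominator see [groupConnectivity()].
#' @param minGroupSize groups below this size are excluded (default 2,
#'   which drops singleton groups such as a one-protein polyW group).
#' @param alpha significance level for the per-group chi-squared flag.
#' @param dunnettControl `"auto"` (mean ratio closest to 1) or a group name.
#' @return list with `results` (one row per analyzed group), `skipped`
#'   (group/reason), `anova`, `dunnett`, `correlation`.
#' @export
analyzeAllGroups <- function(polyx, interactome, universe = NULL,
                             nControls = 5L, seed = 1L, minGroupSize = 2L,
                             alpha = 0.05,
                             chi2Controls = c("mean", "pooled"),
                             denominator = "present_members",
                             dunnettControl = "auto") {
  chi2Controls <- match.arg(chi2Controls)
  groups <- if (is(polyx, "PolyXGroups")) groupMembers(polyx) else polyx
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (is.null(universe))
    universe <- if (is(polyx, "PolyXGroups")) proteomeIds(polyx)
                else nodeIds(interactome)
  sizes <- vapply(groups, function(g) length(unique(g)), integer(1))
  eligible <- names(groups)[sizes >= minGroupSize]
  skipped <- data.frame(group = names(groups)[sizes < minGroupSize],
                        reason = ifelse(
                          sizes[sizes < minGroupSize] == 0,
                          "empty group",
                          paste0("size < ", minGroupSize)),
                        stringsAsFactors = FALSE)
  rows <- list(); ratioSamples <- list()
  for (g in eligible) {
    res <- groupConnectivity(interactome, groups[[g]], universe,
                             nControls, seed, g, chi2Controls, denominator)
    if (inherits(res, "polyXnetSkipped")) {
      skipped <- rbind(skipped,
                       data.frame(group = g, reason = res$reason,
                                  stringsAsFactors = FALSE))
      next
    }
    ratioSamples[[g]] <- res$norm_per_node$ratios
    row <- data.frame(
      residue = g, n_members = res$n_members, n_present = res$n_present,
      type_a = res$type_a, type_b = res$type_b,
      raw_proportion = res$raw_proportion, raw_per_node = res$raw_per_node,
      stringsAsFactors = FALSE)
    for (i in seq_len(nControls)) {
      row[[paste0("norm_prop_", i)]] <- res$norm_proportion$ratios[i]
      row[[paste0("norm_pernode_", i)]] <- res$norm_per_node$ratios[i]
    }
    row$mean_norm_proportion <- res$norm_proportion$mean
    row$sem_norm_proportion <- res$norm_proportion$sem
    row$mean_norm_per_node <- res$norm_per_node$mean
    row$sem_norm_per_node <- res$norm_per_node$sem
    row$chi2_stat <- res$chi2_stat
    row$chi2_p <- res$chi2_p
    row$significant <- !is.na(res$chi2_p) & res$chi2_p < alpha
    rows[[g]] <- row
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  anova <- dunnett <- correlation <- NULL
  if (length(ratioSamples) >= 2) {
    anova <- oneWayAnova(ratioSamples)
    dunnett <- dunnettPosthoc(ratioSamples, control = dunnettControl)
  }
  if (!is.null(results) && nrow(results) >= 3)
    correlation <- pearsonCorrelation(results$mean_norm_proportion,
                                      results$mean_norm_per_node)
  list(results = results, skipped = skipped, anova = anova,
       dunnett = dunnett, correlation = correlation,
       parameters = list(nControls = nControls, seed = seed,
                         minGroupSize = minGroupSize, alpha = alpha,
                         chi2Controls = chi2Controls,
                         denominator = denominator))
}
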