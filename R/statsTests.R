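#' Yates continuity-corrected chi-squared test on a 2x2 of edge counts
#'
#' Compares the type-a / type-b split of a polyX network against a
#' comparison split (typically the averaged or pooled counts of the random
#' control networks).  Delegates to [stats::chisq.test()] with continuity
#' correction (1 df).
#'
#' @param a1,b1 type-a and type-b counts of the group network.
#' @param a2,b2 comparison counts.
#' @return list with `statistic` and `p.value`; both `NA` (with a reason
#'   attribute) when a marginal of the table is zero.
#' @examples
#' yatesChi2Test(10, 20, 30, 40)$statistic  # ~0.4464
#' @export
yatesChi2Test <- function(a1, b1, a2, b2) {
  counts <- c(a1, b1, a2, b2)
  stopifnot(all(counts >= 0), a1 + b1 > 0, a2 + b2 > 0)
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(colSums(m) == 0)) {
    out <- list(statistic = NA_real_, p.value = NA_real_)
    attr(out, "reason") <- "zero marginal"
    return(out)
  }
  ht <- suppressWarnings(chisq.test(m, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value))
}

#' One-way fixed-effects ANOVA over a list of samples
#'
#' Classic equal-variance F test (delegates to [stats::oneway.test()] with
#' `var.equal = TRUE`).  Zero within-group variance with unequal means is
#' reported as an infinite F with p = 0.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return list with `F`, `df_between`, `df_within`, `p.value`.
#' @export
oneWayAnova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  dfB <- length(groups) - 1L
  dfW <- length(values) - length(groups)
  ssw <- sum(tapply(values, fac, function(v) sum((v - mean(v))^2)))
  means <- tapply(values, fac, mean)
  if (ssw == 0) {
    if (max(means) - min(means) == 0)
      stop("zero variance everywhere: ANOVA undefined")
    return(list(F = Inf, df_between = dfB, df_within = dfW, p.value = 0))
  }
  ht <- oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ht$statistic), df_between = dfB, df_within = dfW,
       p.value = unname(ht$p.value))
}

#' Dunnett many-to-one post-hoc comparisons
#'
#' Compares every group against a designated control with familywise
#' adjustment under the equicorrelated multivariate-t reference
#' distribution ([multcomp::glht()] on a one-way fit).  `control = "auto"`
#' picks the group whose mean is closest to 1, the natural reference when
#' the samples are control-normalized ratios.
#'
#' The multivariate-t tail probability is evaluated by quasi-Monte-Carlo;
#' a fixed internal RNG substream makes the adjusted p-values reproducible
#' without touching the caller's RNG state.
#'
#' @param groups named list of numeric samples (>= 2 groups).
#' @param control name or index of the control group, or `"auto"`.
#' @return list with `control` (its name) and `table`: data.frame of
#'   group, estimate (mean difference from control), p_adjusted.
#' @export
dunnettPosthoc <- function(groups, control = "auto") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (identical(control, "auto")) {
    mu <- vapply(groups, mean, numeric(1))
    control <- names(groups)[which.min(abs(mu - 1))]
  } else if (is.numeric(control)) {
    control <- names(groups)[control]
  }
  stopifnot(control %in% names(groups))
  if (sd(groups[[control]]) == 0 && length(groups[[control]]) < 2)
    stop("degenerate control group")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                levels = c(control, setdiff(names(groups), control)))
  fit <- stats::aov(values ~ fac, data = data.frame(values, fac))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(fac = "Dunnett"))
  sm <- withSeed(20151218L, summary(gl))
  cmp <- sub(" - .*$", "", rownames(sm$linfct))
  list(control = control,
       table = data.frame(group = cmp,
                          estimate = unname(sm$test$coefficients),
                          p_adjusted = unname(as.numeric(sm$test$pvalues)),
                          stringsAsFactors = FALSE))
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `n`, `p.value`.
#' @export
pearsonCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), n = length(x), p.value = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] (method `"BH"`) with input
#' validation; returns adjusted values in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order, each <= 1.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
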