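#' Read per-protein domain annotations
#'
#' Expects a TSV with header columns `protein_id`, `domain_id` and optional
#' 1-based inclusive `start`, `end` coordinates (CDD batch-search style).
#' Rows with malformed coordinates (non-numeric, or start > end) are
#' rejected with a message; exact duplicates are collapsed.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with columns protein_id, domain_id, start, end
#'   (coordinates `NA` when absent).  Attribute `rejected` carries the
#'   number of dropped rows.
#' @export
readDomainAnnotations <- function(path) {
  if (!file.exists(path)) stop("domain annotation file not found: ", path)
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    check.names = FALSE)
  req <- c("protein_id", "domain_id")
  if (!all(req %in% names(raw)))
    stop("annotation file lacks required columns: ",
         paste(setdiff(req, names(raw)), collapse = ", "))
  rawStart <- if ("start" %in% names(raw)) raw$start
              else rep("", nrow(raw))
  rawEnd <- if ("end" %in% names(raw)) raw$end else rep("", nrow(raw))
  start <- suppressWarnings(as.integer(rawStart))
  end <- suppressWarnings(as.integer(rawEnd))
  hasCoord <- rawStart != "" | rawEnd != ""
  bad <- (hasCoord & (is.na(start) | is.na(end))) |
         (!is.na(start) & !is.na(end) & start > end) |
         raw$protein_id == "" | raw$domain_id == ""
  if (any(bad)) message(sum(bad), " malformed annotation row(s) rejected")
  df <- data.frame(protein_id = raw$protein_id, domain_id = raw$domain_id,
                   start = start, end = end,
                   stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "rejected") <- sum(bad)
  df
}

#' Hypergeometric domain-overrepresentation test for one protein group
#'
#' For every domain annotated on at least one group member, tests whether
#' the domain is overrepresented in the group relative to the background:
#' the one-sided tail P(X >= k) of the hypergeometric distribution with
#' `N` background proteins, `K` of them carrying the domain, and a draw of
#' `n` group proteins containing `k` carriers.  `mode = "ease"` decrements
#' k by one before taking the tail (DAVID's conservative EASE variant).
#' Raw p-values are Benjamini-Hochberg adjusted within the group's family.
#'
#' @param group character vector of group member ids (subset of
#'   `background`).
#' @param annotations annotation data.frame ([readDomainAnnotations()]).
#' @param background character vector of background protein ids.
#' @param mode `"standard"` or `"ease"`.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame with one row per domain: domain_id, k, n, K, N, fold,
#'   p_raw, p_bh, significant; sorted by p_bh then domain_id.
#' @export
hypergeomEnrichment <- function(group, annotations, background,
                                mode = c("standard", "ease"), alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(background) > 0)
  group <- unique(group); background <- unique(background)
  if (length(setdiff(group, background)))
    stop("group contains ids outside the background")
  ann <- unique(annotations[, c("protein_id", "domain_id")])
  outside <- !(ann$protein_id %in% background)
  if (any(outside)) {
    warning(sum(outside), " annotation(s) on proteins outside the ",
            "background skipped")
    ann <- ann[!outside, , drop = FALSE]
  }
  inGroup <- ann$protein_id %in% group
  domains <- sort(unique(ann$domain_id[inGroup]))
  if (!length(domains))
    return(data.frame(domain_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      p_raw = numeric(), p_bh = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  N <- length(background); n <- length(group)
  K <- vapply(domains, function(d) sum(ann$domain_id == d), integer(1))
  k <- vapply(domains, function(d) sum(ann$domain_id == d & inGroup),
              integer(1))
  kTest <- if (mode == "ease") pmax(k - 1L, 0L) else k
  pRaw <- phyper(kTest - 1, K, N - K, n, lower.tail = FALSE)
  pBh <- bhAdjust(pRaw)
  out <- data.frame(domain_id = domains, k = k, n = n, K = K, N = N,
                    fold = (k / n) / (K / N), p_raw = pRaw, p_bh = pBh,
                    significant = pBh < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_bh, out$domain_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Domain-overrepresentation tests for every polyX group
#'
#' Runs [hypergeomEnrichment()] per group (the BH family is the set of
#' domains tested within one group, mirroring per-list enrichment runs).
#'
#' @param polyx a [PolyXGroups] object or a named list of id vectors.
#' @param annotations annotation data.frame.
#' @param background background ids; default: all proteome ids (for a
#'   [PolyXGroups]); `"annotated"` restricts to proteins carrying at least
#'   one annotation.
#' @param minGroupSize groups below this size are skipped (default 2).
#' @inheritParams hypergeomEnrichment
#' @return data.frame of all groups' records with a leading `residue`
#'   column, sorted by (residue, p_bh).
#' @export
enrichAllGroups <- function(polyx, annotations, background = NULL,
                            mode = c("standard", "ease"), alpha = 0.05,
                            minGroupSize = 2L) {
  mode <- match.arg(mode)
  groups <- if (is(polyx, "PolyXGroups")) groupMembers(polyx) else polyx
  if (is.null(background))
    background <- if (is(polyx, "PolyXGroups")) proteomeIds(polyx)
                  else unique(annotations$protein_id)
  if (identical(background, "annotated"))
    background <- unique(annotations$protein_id)
  res <- lapply(names(groups), function(g) {
    mem <- intersect(unique(groups[[g]]), background)
    if (length(mem) < minGroupSize) return(NULL)
    tab <- hypergeomEnrichment(mem, annotations, background, mode, alpha)
    if (!nrow(tab)) return(NULL)
    cbind(residue = g, tab, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(residue = character(), domain_id = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p_raw = numeric(),
                      p_bh = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$residue, out$p_bh, out$domain_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
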