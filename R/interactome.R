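#' Build an Interactome from an edge data.frame
#'
#' Canonicalizes orientation, collapses duplicate and reversed-duplicate
#' rows, and drops (or sets aside) self-interactions.
#'
#' @param edges data.frame or matrix whose first two columns are interactor
#'   ids.
#' @param keepSelfLoops if `TRUE`, self-interactions are retained in the
#'   `selfNodes` slot and count as one type-a edge for their node in
#'   [extractGroupNetwork()].
#' @return an [Interactome].
#' @export
makeInteractome <- function(edges, keepSelfLoops = FALSE) {
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  ok <- !is.na(a) & !is.na(b) & a != "" & b != ""
  a <- a[ok]; b <- b[ok]
  selfIdx <- a == b
  selfNodes <- if (keepSelfLoops) unique(a[selfIdx]) else character()
  a2 <- pmin(a[!selfIdx], b[!selfIdx])
  b2 <- pmax(a[!selfIdx], b[!selfIdx])
  key <- paste(a2, b2, sep = "\r")
  keep <- !duplicated(key)
  e <- cbind(a2[keep], b2[keep])
  ord <- order(e[, 1], e[, 2])
  e <- e[ord, , drop = FALSE]
  colnames(e) <- c("protein_a", "protein_b")
  new("Interactome", edges = e,
      nodes = unique(c(e[, 1], e[, 2], selfNodes)),
      selfNodes = selfNodes)
}

#' Read a binary protein-protein interaction edge list
#'
#' Supports a headerless (or headered) two-column TSV and BioGRID TAB-style
#' files where the interactor columns are named.  The graph is undirected
#' and simple: duplicate rows, reversed duplicates and (by default)
#' self-interactions are collapsed or dropped.  Rows with missing ids are
#' skipped and counted.
#'
#' @param path path to the TSV file.
#' @param format `"two_column"` or `"biogrid_tab"`.
#' @param colA,colB interactor column names for `biogrid_tab` (defaults are
#'   the BioGRID official-symbol columns).
#' @param keepSelfLoops see [makeInteractome()].
#' @return an [Interactome]; an attribute `skipped` carries the number of
#'   unparseable rows.
#' @export
readInteractions <- function(path, format = c("two_column", "biogrid_tab"),
                             colA = "Official Symbol Interactor A",
                             colB = "Official Symbol Interactor B",
                             keepSelfLoops = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("interaction file not found: ", path)
  if (format == "two_column") {
    if (length(readLines(path, n = 1)) == 0)
      stop("zero edges after filtering: ", path)
    raw <- read.delim(path, header = FALSE, colClasses = "character",
                      comment.char = "#", blank.lines.skip = TRUE)
    if (nrow(raw) && !ncol(raw) >= 2)
      stop("two_column format requires at least two columns")
    # tolerate an optional header row
    if (nrow(raw) && tolower(raw[1, 1]) %in%
        c("protein_a", "interactor_a", "interactor a"))
      raw <- raw[-1, , drop = FALSE]
    df <- raw[, 1:2, drop = FALSE]
  } else {
    raw <- read.delim(path, header = TRUE, colClasses = "character",
                      check.names = FALSE)
    if (!all(c(colA, colB) %in% names(raw)))
      stop("biogrid_tab file lacks columns: ",
           paste(setdiff(c(colA, colB), names(raw)), collapse = ", "))
    df <- raw[, c(colA, colB)]
  }
  bad <- !complete.cases(df) | df[[1]] == "" | df[[2]] == ""
  if (any(bad)) {
    message(sum(bad), " unparseable interaction row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  inter <- makeInteractome(df, keepSelfLoops = keepSelfLoops)
  if (edgeCount(inter) == 0 && length(inter@selfNodes) == 0)
    stop("zero edges after filtering: ", path)
  attr(inter, "skipped") <- sum(bad)
  inter
}

#' Extract and classify a protein group's interaction network
#'
#' Classifies every interactome edge incident to the group: type a if both
#' endpoints are members, type b if exactly one is.  Edges between two
#' non-members are discarded.  Membership is tested on the id string only;
#' ids absent from the interactome simply contribute no edges.
#'
#' @param interactome an [Interactome].
#' @param group character vector of member ids (non-empty).
#' @return a [GroupNetwork].
#' @export
extractGroupNetwork <- function(interactome, group) {
  stopifnot(is(interactome, "Interactome"), length(group) > 0)
  group <- unique(as.character(group))
  e <- interactome@edges
  in1 <- e[, 1] %in% group
  in2 <- e[, 2] %in% group
  a <- e[in1 & in2, , drop = FALSE]
  b <- e[xor(in1, in2), , drop = FALSE]
  selfA <- intersect(interactome@selfNodes, group)
  if (length(selfA))
    a <- rbind(a, cbind(selfA, selfA))
  bMember <- ifelse(b[, 1] %in% group, b[, 1], b[, 2])
  present <- intersect(group, unique(c(a[, 1], a[, 2], bMember)))
  new("GroupNetwork", group = group, typeA = a, typeB = b,
      presentMembers = present)
}

#' Per-member count of within-group (type-a) interactions
#'
#' @param gn a [GroupNetwork].
#' @return named integer vector over all group members (zeros included);
#'   its sum equals twice the number of type-a edges (self-interactions,
#'   if retained, count once).
#' @export
withinGroupDegrees <- function(gn) {
  stopifnot(is(gn, "GroupNetwork"))
  deg <- setNames(integer(length(gn@group)), gn@group)
  a <- gn@typeA
  if (nrow(a)) {
    self <- a[, 1] == a[, 2]
    tab <- table(c(a[!self, 1], a[!self, 2], a[self, 1]))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}
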