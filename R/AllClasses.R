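#' @include polyXnet-package.R
NULL

#' Interactome: an undirected simple protein-protein interaction graph
#'
#' Edges are stored as a two-column character matrix in canonical order
#' (first id lexicographically smaller), one row per unordered pair.
#' Self-interactions dropped at read time may optionally be retained in the
#' `selfNodes` slot (see [readInteractions()]).
#'
#' @slot edges two-column character matrix of distinct unordered pairs.
#' @slot nodes character vector of protein ids appearing in at least one edge.
#' @slot selfNodes ids with a retained self-interaction (empty by default).
#'
#' @exportClass Interactome
setClass("Interactome",
         representation(edges = "matrix",
                        nodes = "character",
                        selfNodes = "character"))

setValidity("Interactome", function(object) {
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2)
    return("edges must be a two-column character matrix")
  if (nrow(e)) {
    if (any(e[, 1] >= e[, 2]))
      return("edges must be in canonical order (col1 < col2) with no self-pairs")
    if (anyDuplicated(paste(e[, 1], e[, 2], sep = "\r")))
      return("duplicate edges present")
  }
  if (!setequal(object@nodes, unique(c(e[, 1], e[, 2], object@selfNodes))))
    return("nodes slot inconsistent with edge endpoints")
  TRUE
})

#' GroupNetwork: a protein group's interaction neighbourhood, edges classified
#'
#' Type-a edges join two group members; type-b edges join a member to a
#' non-member.  Edges between two non-members are not retained.
#'
#' @slot group character vector of member ids.
#' @slot typeA,typeB two-column character edge matrices.
#' @slot presentMembers members incident to at least one retained edge.
#'
#' @exportClass GroupNetwork
setClass("GroupNetwork",
         representation(group = "character",
                        typeA = "matrix",
                        typeB = "matrix",
                        presentMembers = "character"))

setValidity("GroupNetwork", function(object) {
  a <- object@typeA; b <- object@typeB
  if (nrow(a) && !all(a %in% c(object@group)))
    return("type-a edge with an endpoint outside the group")
  if (nrow(b)) {
    inG1 <- b[, 1] %in% object@group
    inG2 <- b[, 2] %in% object@group
    if (!all(xor(inG1, inG2)))
      return("type-b edge must have exactly one endpoint in the group")
  }
  if (length(setdiff(object@presentMembers, object@group)))
    return("presentMembers must be a subset of the group")
  TRUE
})

#' PolyXGroups: the 20 polyX protein groups of a proteome
#'
#' One group per standard residue X: the proteins carrying at least one
#' maximal run of X of length >= `minRunLength`.  Per-protein run
#' coordinates are retained for the repeat/domain overlap analysis.
#'
#' @slot groups named list (the 20 residues, possibly empty members).
#' @slot repeats data.frame of all runs: protein_id, residue, start, end,
#'   length (1-based inclusive coordinates).
#' @slot minRunLength integer run-length threshold used for the scan.
#' @slot universe all protein ids of the scanned proteome.
#'
#' @exportClass PolyXGroups
setClass("PolyXGroups",
         representation(groups = "list",
                        repeats = "data.frame",
                        minRunLength = "integer",
                        universe = "character"))

setValidity("PolyXGroups", function(object) {
  if (!identical(sort(names(object@groups)), sort(AA_STANDARD)))
    return("groups must be named by the 20 standard residues")
  req <- c("protein_id", "residue", "start", "end", "length")
  if (!all(req %in% names(object@repeats)))
    return("repeats table missing required columns")
  bad <- vapply(AA_STANDARD, function(x)
    length(setdiff(object@groups[[x]], object@universe)) > 0, logical(1))
  if (any(bad)) return("group member outside the proteome universe")
  TRUE
})
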