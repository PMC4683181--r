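#' @include AllClasses.R
NULL

#' @rdname Interactome-class
#' @param x an object.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname Interactome-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname Interactome-class
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname GroupNetwork-class
#' @param x an object.
#' @export
setGeneric("typeA", function(x) standardGeneric("typeA"))

#' @rdname GroupNetwork-class
#' @export
setGeneric("typeB", function(x) standardGeneric("typeB"))

#' @rdname GroupNetwork-class
#' @export
setGeneric("presentMembers", function(x) standardGeneric("presentMembers"))

#' @rdname GroupNetwork-class
#' @param ... passed to methods.
#' @export
setGeneric("groupMembers", function(x, ...) standardGeneric("groupMembers"))

#' @rdname PolyXGroups-class
#' @export
setGeneric("repeatTable", function(x) standardGeneric("repeatTable"))

#' @rdname PolyXGroups-class
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname PolyXGroups-class
#' @export
setGeneric("proteomeIds", function(x) standardGeneric("proteomeIds"))

## --- Interactome methods ---------------------------------------------------

#' @rdname Interactome-class
#' @export
setMethod("nodeIds", "Interactome", function(x) x@nodes)

#' @rdname Interactome-class
#' @export
setMethod("edgeTable", "Interactome", function(x) {
  data.frame(protein_a = x@edges[, 1], protein_b = x@edges[, 2],
             stringsAsFactors = FALSE)
})

#' @rdname Interactome-class
#' @export
setMethod("edgeCount", "Interactome", function(x) nrow(x@edges))

setMethod("show", "Interactome", function(object) {
  cat("Interactome with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges")
  if (length(object@selfNodes))
    cat(" (", length(object@selfNodes), " self-interactions retained)",
        sep = "")
  cat("\n")
})

## --- GroupNetwork methods --------------------------------------------------

#' @rdname GroupNetwork-class
#' @export
setMethod("typeA", "GroupNetwork", function(x) x@typeA)

#' @rdname GroupNetwork-class
#' @export
setMethod("typeB", "GroupNetwork", function(x) x@typeB)

#' @rdname GroupNetwork-class
#' @export
setMethod("presentMembers", "GroupNetwork", function(x) x@presentMembers)

#' @rdname GroupNetwork-class
#' @export
setMethod("groupMembers", "GroupNetwork", function(x, ...) x@group)

setMethod("show", "GroupNetwork", function(object) {
  cat("GroupNetwork:", length(object@group), "members (",
      length(object@presentMembers), "with interactions ),",
      nrow(object@typeA), "type-a and", nrow(object@typeB), "type-b edges\n")
})

## --- PolyXGroups methods ---------------------------------------------------

#' @rdname PolyXGroups-class
#' @param x a `PolyXGroups` object.
#' @param residue single residue letter; if missing, the full named list is
#'   returned.
#' @param ... unused.
#' @export
setMethod("groupMembers", "PolyXGroups", function(x, residue, ...) {
  if (missing(residue)) return(x@groups)
  stopifnot(residue %in% AA_STANDARD)
  x@groups[[residue]]
})

#' @rdname PolyXGroups-class
#' @export
setMethod("repeatTable", "PolyXGroups", function(x) x@repeats)

#' @rdname PolyXGroups-class
#' @export
setMethod("groupSizes", "PolyXGroups", function(x) {
  vapply(x@groups[AA_STANDARD], length, integer(1))
})

#' @rdname PolyXGroups-class
#' @export
setMethod("proteomeIds", "PolyXGroups", function(x) x@universe)

setMethod("show", "PolyXGroups", function(object) {
  sz <- groupSizes(object)
  cat("PolyXGroups over", length(object@universe), "proteins",
      "(min run length", object@minRunLength, ")\n")
  cat(" non-empty groups:",
      paste0(names(sz)[sz > 0], ":", sz[sz > 0], collapse = " "), "\n")
})
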