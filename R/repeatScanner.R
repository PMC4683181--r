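#' Read a proteome FASTA
#'
#' Wraps [Biostrings::readAAStringSet()] and applies an id extractor to the
#' FASTA headers.  The default takes the header token up to the first
#' whitespace; `"uniprot"` extracts the accession field of
#' `db|ACCESSION|NAME` style headers.
#'
#' @param path path to a FASTA file (uncompressed or gzip).
#' @param idExtractor `"first_token"`, `"uniprot"`, or a function mapping a
#'   character vector of headers to ids.
#' @return an [Biostrings::AAStringSet] named by protein id.  An empty file
#'   yields an empty set.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 some protein", "MQA", ">P2", "KK"), tf)
#' readProteome(tf)
#' @export
readProteome <- function(path, idExtractor = c("first_token", "uniprot")) {
  if (!file.exists(path)) stop("proteome FASTA not found: ", path)
  if (file.size(path) == 0) return(Biostrings::AAStringSet())
  aa <- Biostrings::readAAStringSet(path)
  if (is.function(idExtractor)) {
    ids <- idExtractor(names(aa))
  } else {
    idExtractor <- match.arg(idExtractor)
    ids <- switch(idExtractor,
      first_token = sub("\\s.*$", "", names(aa)),
      uniprot = {
        tok <- sub("\\s.*$", "", names(aa))
        ifelse(grepl("^[^|]+\\|[^|]+\\|", tok),
               sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", tok), tok)
      })
  }
  if (any(ids == "")) stop("empty protein id in FASTA header")
  if (anyDuplicated(ids))
    stop("duplicate protein ids in proteome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(aa) == 0))
    stop("empty sequence record(s): ",
         paste(ids[Biostrings::width(aa) == 0], collapse = ", "))
  names(aa) <- ids
  aa
}

#' Find maximal homopolymer runs in one sequence
#'
#' Reports every maximal run of a single standard residue with length at
#' least `minRunLength`, in order of start position.  Runs of non-standard
#' letters (X, U, B, Z, `*`, ...) are never reported, and such letters break
#' runs of standard residues.
#'
#' @param sequence a single amino-acid sequence (character scalar or
#'   `AAString`-coercible).
#' @param minRunLength minimum run length (default 4, the repeat-length
#'   threshold used throughout the package).
#' @return data.frame with columns residue, start, end, length
#'   (1-based inclusive coordinates).
#' @examples
#' findHomopolymerRuns("MQQQQQAPPPPL", 4)
#' @export
findHomopolymerRuns <- function(sequence, minRunLength = 4L) {
  stopifnot(length(sequence) == 1, minRunLength >= 1)
  sequence <- as.character(sequence)
  empty <- data.frame(residue = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) == 0) return(empty)
  r <- rle(strsplit(toupper(sequence), "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= minRunLength & r$values %in% AA_STANDARD
  if (!any(keep)) return(empty)
  data.frame(residue = r$values[keep],
             start = as.integer(starts[keep]),
             end = as.integer(ends[keep]),
             length = as.integer(r$lengths[keep]),
             stringsAsFactors = FALSE)
}

#' Scan a whole proteome for homopolymer runs
#'
#' @param proteome named `AAStringSet` (or named character vector) as
#'   returned by [readProteome()].
#' @inheritParams findHomopolymerRuns
#' @return data.frame with columns protein_id, residue, start, end, length;
#'   one row per maximal run, ordered by protein then start.
#' @export
scanRepeats <- function(proteome, minRunLength = 4L) {
  nm <- names(proteome)
  if (is.null(nm) || any(nm == ""))
    stop("proteome must be named by protein id")
  seqs <- as.character(proteome)
  names(seqs) <- nm
  runs <- lapply(names(seqs), function(id) {
    df <- findHomopolymerRuns(seqs[[id]], minRunLength)
    if (nrow(df)) cbind(protein_id = id, df, stringsAsFactors = FALSE)
    else NULL
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (!length(runs))
    return(data.frame(protein_id = character(), residue = character(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, runs)
}

#' Define the 20 polyX protein groups
#'
#' A protein belongs to group X iff it carries at least one maximal run of
#' residue X of length >= `minRunLength`; a protein may belong to several
#' groups.  All 20 groups are present in the result, possibly empty.
#'
#' @inheritParams scanRepeats
#' @return a [PolyXGroups] object.
#' @examples
#' prot <- c(P1 = "MQQQQA", P2 = "AAAAQQ", P3 = "MLLLLL")
#' groupSizes(buildPolyXGroups(prot))[c("Q", "A", "L")]
#' @export
buildPolyXGroups <- function(proteome, minRunLength = 4L) {
  if (length(proteome) == 0) stop("proteome is empty")
  reps <- scanRepeats(proteome, minRunLength)
  groups <- lapply(AA_STANDARD, function(x)
    unique(reps$protein_id[reps$residue == x]))
  names(groups) <- AA_STANDARD
  new("PolyXGroups", groups = groups, repeats = reps,
      minRunLength = as.integer(minRunLength),
      universe = names(proteome))
}

#' Write repeat-scan artifacts
#'
#' `writeRepeatsTsv` writes one row per maximal run (1-based inclusive
#' coordinates); `writeGroupsTsv` writes one row per residue with the member
#' count and comma-separated member ids.
#'
#' @param polyx a [PolyXGroups] object.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeRepeatsTsv <- function(polyx, path) {
  writeTsv(repeatTable(polyx), path)
}

#' @rdname writeRepeatsTsv
#' @export
writeGroupsTsv <- function(polyx, path) {
  g <- groupMembers(polyx)
  writeTsv(data.frame(
    residue = AA_STANDARD,
    n_proteins = vapply(g[AA_STANDARD], length, integer(1)),
    members = vapply(g[AA_STANDARD],
                     function(m) paste(sort(m), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE), path)
}
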