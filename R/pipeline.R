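stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

fmtNum <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 10, format = "g") else as.character(x)
}

#' Export a group network for graph viewers
#'
#' `edge_tsv` writes protein_a, protein_b, edge_type (`a`/`b`); the file
#' round-trips through [readInteractions()] (the type column is ignored
#' there).  `graphml` writes an igraph GraphML file with a logical
#' `member` node attribute and a `type` edge attribute, loadable by
#' Cytoscape-class tools.
#'
#' @param gn a [GroupNetwork] with at least one edge.
#' @param path output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return the path, invisibly.
#' @export
writeNetworkExport <- function(gn, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  a <- typeA(gn); b <- typeB(gn)
  if (nrow(a) + nrow(b) == 0) stop("cannot export an empty network")
  edges <- data.frame(
    protein_a = c(a[, 1], b[, 1]), protein_b = c(a[, 2], b[, 2]),
    edge_type = c(rep("a", nrow(a)), rep("b", nrow(b))),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$edge_type, edges$protein_a, edges$protein_b), ]
  rownames(edges) <- NULL
  if (format == "edge_tsv") return(writeTsv(edges, path))
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")], directed = FALSE,
    vertices = data.frame(name = nodes,
                          member = nodes %in% groupMembers(gn)))
  igraph::E(g)$type <- edges$edge_type
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

summaryStatsTable <- function(conn) {
  rows <- list()
  add <- function(section, name, value)
    rows[[length(rows) + 1]] <<- data.frame(
      section = section, name = name, value = fmtNum(value),
      stringsAsFactors = FALSE)
  if (!is.null(conn$anova)) {
    add("anova", "F", conn$anova$F)
    add("anova", "df_between", conn$anova$df_between)
    add("anova", "df_within", conn$anova$df_within)
    add("anova", "p", conn$anova$p.value)
  }
  if (!is.null(conn$dunnett)) {
    add("dunnett", "control_group", conn$dunnett$control)
    for (i in seq_len(nrow(conn$dunnett$table)))
      add("dunnett", paste0("p_adj_", conn$dunnett$table$group[i]),
          conn$dunnett$table$p_adjusted[i])
  }
  if (!is.null(conn$correlation)) {
    add("pearson", "r", conn$correlation$r)
    add("pearson", "n", conn$correlation$n)
    add("pearson", "p", conn$correlation$p.value)
  }
  if (nrow(conn$skipped))
    for (i in seq_len(nrow(conn$skipped)))
      add("skipped", conn$skipped$group[i], conn$skipped$reason[i])
  do.call(rbind, rows)
}

#' Run the complete analysis pipeline
#'
#' scan -> polyX groups -> group networks -> control-normalized
#' connectivity and statistics -> domain enrichment -> repeat/domain
#' overlap, writing every artifact plus a reproducibility manifest to
#' `outDir`.  Identical inputs, parameters and seed give byte-identical
#' output files.
#'
#' @param proteomePath proteome FASTA.
#' @param interactomePath binary-interaction TSV (see
#'   [readInteractions()]).
#' @param domainsPath domain-annotation TSV, or `NULL` to skip the
#'   enrichment and overlap stages.
#' @param outDir output directory (created).
#' @param minRunLength repeat-length threshold (default 4).
#' @param nControls random control groups per polyX group (default 5).
#' @param seed master seed for all randomness.
#' @param alpha significance level (default 0.05).
#' @param chi2Controls,perNodeDenominator,minGroupSize,dunnettControl see
#'   [analyzeAllGroups()].
#' @param enrichmentMode,background see [enrichAllGroups()].
#' @param minOverlap repeat/domain overlap threshold in residues
#'   (default 4).
#' @param overlapAllPairs evaluate all co-occurring repeat-domain pairs
#'   rather than only significant ones.
#' @param interactionFormat,interactionColA,interactionColB passed to
#'   [readInteractions()].
#' @param idExtractor passed to [readProteome()].
#' @param writeNetworks write per-group edge TSVs under `networks/`.
#' @return invisible list of the in-memory results (`polyx`,
#'   `interactome`, `connectivity`, `enrichment`, `overlap`, `paths`).
#' @export
runFullAnalysis <- function(proteomePath, interactomePath,
                            domainsPath = NULL, outDir,
                            minRunLength = 4L, nControls = 5L, seed = 1L,
                            alpha = 0.05,
                            chi2Controls = c("mean", "pooled"),
                            perNodeDenominator = "present_members",
                            minGroupSize = 2L, dunnettControl = "auto",
                            enrichmentMode = "standard", background = NULL,
                            minOverlap = 4L, overlapAllPairs = FALSE,
                            interactionFormat = "two_column",
                            interactionColA = "Official Symbol Interactor A",
                            interactionColB = "Official Symbol Interactor B",
                            idExtractor = "first_token",
                            writeNetworks = TRUE) {
  chi2Controls <- match.arg(chi2Controls)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outDir, f)

  proteome <- stageTry("read_proteome",
                       readProteome(proteomePath, idExtractor))
  polyx <- stageTry("repeat_scan", buildPolyXGroups(proteome, minRunLength))
  writeRepeatsTsv(polyx, p("repeats.tsv"))
  writeGroupsTsv(polyx, p("groups.tsv"))

  inter <- stageTry("read_interactions",
                    readInteractions(interactomePath, interactionFormat,
                                     interactionColA, interactionColB))
  sharedIds <- mean(nodeIds(inter) %in% proteomeIds(polyx))
  if (sharedIds < 0.5)
    warning(sprintf(
      "only %.1f%% of interactome nodes match a proteome id; %s",
      100 * sharedIds,
      "are the two inputs in the same id namespace?"))

  conn <- stageTry("connectivity",
                   analyzeAllGroups(polyx, inter, nControls = nControls,
                                    seed = seed, minGroupSize = minGroupSize,
                                    alpha = alpha,
                                    chi2Controls = chi2Controls,
                                    denominator = perNodeDenominator,
                                    dunnettControl = dunnettControl))
  if (!is.null(conn$results)) writeTsv(conn$results, p("connectivity.tsv"))
  writeTsv(summaryStatsTable(conn), p("summary_stats.tsv"))

  if (writeNetworks && !is.null(conn$results)) {
    dir.create(p("networks"), showWarnings = FALSE)
    for (g in conn$results$residue) {
      gn <- extractGroupNetwork(inter, groupMembers(polyx, g))
      if (nrow(typeA(gn)) + nrow(typeB(gn)) > 0)
        writeNetworkExport(gn, p(file.path("networks",
                                           paste0("group_", g, ".tsv"))))
    }
  }

  enrichment <- overlap <- NULL
  if (!is.null(domainsPath)) {
    ann <- stageTry("read_domains", readDomainAnnotations(domainsPath))
    enrichment <- stageTry("enrichment",
                           enrichAllGroups(polyx, ann,
                                           background = background,
                                           mode = enrichmentMode,
                                           alpha = alpha,
                                           minGroupSize = minGroupSize))
    writeTsv(enrichment, p("enrichment.tsv"))
    overlap <- stageTry("overlap",
                        overlapAnalysis(repeatTable(polyx), ann,
                                        enrichment = enrichment,
                                        minOverlap = minOverlap,
                                        allPairs = overlapAllPairs))
    writeTsv(overlap, p("overlap.tsv"))
  }

  inputs <- c(proteome = proteomePath, interactome = interactomePath)
  if (!is.null(domainsPath)) inputs["domains"] <- domainsPath
  manifest <- list(
    package = "polyXnet",
    version = as.character(utils::packageVersion("polyXnet")),
    seed = seed,
    parameters = list(
      min_run_length = minRunLength, n_controls = nControls,
      alpha = alpha, chi2_controls = chi2Controls,
      per_node_denominator = perNodeDenominator,
      min_group_size = minGroupSize, dunnett_control = dunnettControl,
      enrichment_mode = enrichmentMode,
      background = if (is.null(background)) "proteome" else background,
      min_overlap = minOverlap, overlap_all_pairs = overlapAllPairs,
      interaction_format = interactionFormat,
      id_extractor = if (is.function(idExtractor)) "custom" else idExtractor),
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(unname(inputs))))
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(polyx = polyx, interactome = inter, connectivity = conn,
                 enrichment = enrichment, overlap = overlap,
                 paths = normalizePath(outDir)))
}
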