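#' Filter a differential-expression table to significant genes
#'
#' Inclusion rule: FDR < `fdr_max` (0.05) AND |log2FC| > `log2fc_min`
#' (1.1), both strict. Genes are partitioned by the sign of log2FC.
#'
#' @param deg data.frame with columns `gene_id`, `log2fc`, `fdr`.
#' @param cfg an [analysis_config()].
#' @return List with `genes` (all passing genes), `up`, `down`.
#' @export
filter_degs <- function(deg, cfg = analysis_config()) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(deg)))
  if (anyDuplicated(deg$gene_id)) stop("filter_degs: duplicated gene_id rows")
  if (any(!is.finite(deg$log2fc)) || any(!is.finite(deg$fdr))) {
    stop("filter_degs: log2fc and fdr must be finite")
  }
  pass <- deg$fdr < cfg$network$fdr_max &
    abs(deg$log2fc) > cfg$network$log2fc_min
  list(genes = deg$gene_id[pass],
       up = deg$gene_id[pass & deg$log2fc > 0],
       down = deg$gene_id[pass & deg$log2fc < 0])
}

#' Overlap coefficient between two gene sets
#'
#' The average of the shared-gene count divided by the size of each set:
#' `OC = (|A&B|/|A| + |A&B|/|B|) / 2`. Symmetric, in `[0, 1]`, 1 iff the
#' sets are equal, 0 iff disjoint.
#'
#' @param a,b character vectors of gene identifiers (case-sensitive; no
#'   symbol aliasing is applied).
#' @return The overlap coefficient.
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("overlap_coefficient: empty gene set")
  }
  shared <- length(intersect(a, b))
  (shared / length(a) + shared / length(b)) / 2
}

#' Over-representation of gene sets among differentially expressed genes
#'
#' For each set, counts the DEG hits and computes the upper-tail
#' hypergeometric probability of at least that many hits when DEGs are
#' drawn uniformly from the universe, with Benjamini-Hochberg adjustment
#' across sets. (The published analysis used an external enrichment
#' service; this is the standard self-contained equivalent.)
#'
#' @param genesets named list of gene-id vectors.
#' @param degs character vector of differentially expressed gene ids.
#' @param universe character vector of all candidate gene ids; sets and
#'   DEGs outside it are intersected into it with a warning.
#' @return data.frame: `set_id`, `set_size`, `deg_hits`, `p_value`,
#'   `enrich_fdr`.
#' @export
enrich_genesets <- function(genesets, degs, universe) {
  stopifnot(length(genesets) >= 1, length(universe) >= 1)
  universe <- unique(universe)
  degs <- unique(degs)
  if (!all(degs %in% universe)) {
    warning("enrich_genesets: DEGs outside universe dropped")
    degs <- intersect(degs, universe)
  }
  if (!all(unlist(genesets) %in% universe)) {
    warning("enrich_genesets: gene-set members outside universe dropped")
    genesets <- lapply(genesets, intersect, universe)
  }
  n_u <- length(universe); n_d <- length(degs)
  out <- do.call(rbind, lapply(names(genesets), function(id) {
    s <- unique(genesets[[id]])
    hits <- length(intersect(s, degs))
    p <- stats::phyper(hits - 1, length(s), n_u - length(s), n_d,
                       lower.tail = FALSE)
    data.frame(set_id = id, set_size = length(s), deg_hits = hits,
               p_value = p)
  }))
  out$enrich_fdr <- benjamini_hochberg(out$p_value)
  out
}

#' Build the gene-set enrichment network
#'
#' Nodes are the gene sets over-represented among the DEGs (enrichment
#' FDR < `fdr_max`), sized by their DEG hit count; an edge connects two
#' sets when their overlap coefficient is at least `oc_min` (0.3,
#' inclusive), weighted by the number of shared genes.
#'
#' @param genesets named list of gene-id vectors.
#' @param degs character vector of DEG ids (e.g. `filter_degs()$genes`).
#' @param universe character vector of all candidate gene ids.
#' @param cfg an [analysis_config()].
#' @return List of class `enrich_network`: `nodes` (set_id, set_size,
#'   deg_hits, enrich_fdr), `edges` (set_i, set_j, oc, shared), `graph`
#'   (an igraph object).
#' @export
build_network <- function(genesets, degs, universe,
                          cfg = analysis_config()) {
  enr <- enrich_genesets(genesets, degs, universe)
  nodes <- enr[enr$enrich_fdr < cfg$network$fdr_max, ]
  rownames(nodes) <- NULL
  sets <- genesets[nodes$set_id]

  edges <- data.frame(set_i = character(0), set_j = character(0),
                      oc = numeric(0), shared = integer(0))
  if (nrow(nodes) >= 2) {
    for (i in seq_len(nrow(nodes) - 1L)) {
      for (j in (i + 1L):nrow(nodes)) {
        sh <- length(intersect(unique(sets[[i]]), unique(sets[[j]])))
        oc <- overlap_coefficient(sets[[i]], sets[[j]])
        if (oc >= cfg$network$oc_min && sh > 0) {
          edges <- rbind(edges, data.frame(
            set_i = nodes$set_id[i], set_j = nodes$set_id[j],
            oc = oc, shared = sh))
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(set_i = character(0),
                                           set_j = character(0)),
    directed = FALSE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "enrich_network")
}

#' @export
print.enrich_network <- function(x, ...) {
  cat(sprintf("<enrich_network> %d significant sets, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write an enrichment network as GraphML and JSON
#'
#' @param network an [build_network()] result.
#' @param path_graphml,path_json output paths (either may be `NULL`).
#' @return Invisibly, the network.
#' @export
write_network <- function(network, path_graphml = NULL, path_json = NULL) {
  stopifnot(inherits(network, "enrich_network"))
  if (!is.null(path_graphml)) {
    igraph::write_graph(network$graph, path_graphml, format = "graphml")
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(nodes = network$nodes, edges = network$edges),
                         path_json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(network)
}
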