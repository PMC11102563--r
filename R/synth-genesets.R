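#' Simulate gene sets with exact pairwise overlap coefficients
#'
#' Builds `n_sets` equal-size gene sets over a synthetic universe so that
#' every realized pairwise overlap coefficient equals the requested
#' `overlap_matrix` entry exactly: each pair with a non-zero target gets a
#' dedicated, disjoint block of shared genes (so higher-order overlaps are
#' zero) and sets are padded with unique genes to `set_size`. For equal set
#' sizes the overlap coefficient is `shared / set_size`, so each requested
#' coefficient must be a multiple of `1 / set_size`.
#'
#' A differential-expression table covering the whole universe accompanies
#' the sets: a controlled fraction of genes passes the inclusion rule
#' FDR < 0.05 and |log2FC| > 1.1, with in-set genes enriched by
#' `enrichment_factor` so that the sets score as over-represented.
#'
#' @param n_sets number of gene sets.
#' @param universe_size total genes in the synthetic universe.
#' @param overlap_matrix symmetric `n_sets x n_sets` matrix of target
#'   overlap coefficients (diagonal ignored); `NULL` for all-zero.
#' @param deg_fraction probability a gene outside every set is
#'   differentially expressed.
#' @param seed integer seed.
#' @param set_size genes per set.
#' @param enrichment_factor multiplier on `deg_fraction` for in-set genes
#'   (capped at 1).
#' @return List with `sets` (named list of gene-id vectors), `deg`
#'   (data.frame: `gene_id`, `log2fc`, `fdr`), `universe`, and `truth`
#'   (which genes are DEGs, per-set hit counts, the realized shared counts).
#' @export
gen_genesets <- function(n_sets = 6L, universe_size = 2000L,
                         overlap_matrix = NULL, deg_fraction = 0.1,
                         seed = NULL, set_size = 40L,
                         enrichment_factor = 5) {
  n_sets <- as.integer(n_sets)
  stopifnot(n_sets >= 1, set_size >= 1, universe_size >= n_sets * set_size,
            deg_fraction >= 0, deg_fraction <= 1)
  if (is.null(overlap_matrix)) {
    overlap_matrix <- matrix(0, n_sets, n_sets)
  }
  oc <- as.matrix(overlap_matrix)
  stopifnot(nrow(oc) == n_sets, ncol(oc) == n_sets)
  if (any(oc < 0 | oc > 1, na.rm = TRUE) || !isSymmetric(unname(oc))) {
    stop("overlap_matrix must be symmetric with entries in [0, 1]")
  }
  shared <- round(oc * set_size)
  diag(shared) <- 0
  if (any(abs(oc * set_size - round(oc * set_size))[upper.tri(oc)] > 1e-9)) {
    stop("infeasible overlap_matrix: each coefficient must be a multiple of 1/set_size")
  }
  if (any(rowSums(shared) > set_size)) {
    stop("infeasible overlap_matrix: pairwise shared genes exceed set_size for some set")
  }

  ids <- sprintf("g%05d", seq_len(universe_size))
  nxt <- 1L
  take <- function(k) {
    out <- ids[nxt:(nxt + k - 1L)]
    nxt <<- nxt + k
    out
  }
  sets <- replicate(n_sets, character(0), simplify = FALSE)
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  for (i in seq_len(n_sets - 1L)) {
    for (j in (i + 1L):n_sets) {
      if (shared[i, j] > 0) {
        block <- take(shared[i, j])
        sets[[i]] <- c(sets[[i]], block)
        sets[[j]] <- c(sets[[j]], block)
      }
    }
  }
  for (i in seq_len(n_sets)) {
    pad <- set_size - length(sets[[i]])
    if (pad > 0) sets[[i]] <- c(sets[[i]], take(pad))
  }

  in_set <- ids %in% unlist(sets)
  p_deg <- ifelse(in_set, min(1, deg_fraction * enrichment_factor),
                  deg_fraction)
  with_seed(seed, {
    is_deg <- stats::runif(universe_size) < p_deg
    log2fc <- numeric(universe_size)
    fdr <- numeric(universe_size)
    nd <- sum(is_deg)
    if (nd > 0) {
      log2fc[is_deg] <- sample(c(-1, 1), nd, replace = TRUE) *
        stats::runif(nd, 1.2, 4)
      fdr[is_deg] <- stats::runif(nd, 1e-6, 0.049)
    }
    nn <- sum(!is_deg)
    if (nn > 0) {
      # non-DEGs fail at least one gate: high FDR, or small fold change
      weak_fc <- stats::runif(nn) < 0.5
      log2fc[!is_deg] <- ifelse(weak_fc, stats::runif(nn, -1, 1),
                                stats::runif(nn, -3, 3))
      fdr[!is_deg] <- ifelse(weak_fc, stats::runif(nn, 0, 1),
                             stats::runif(nn, 0.051, 1))
    }
  })
  deg <- data.frame(gene_id = ids, log2fc = log2fc, fdr = fdr,
                    stringsAsFactors = FALSE)
  hits <- vapply(sets, function(s) sum(s %in% ids[is_deg]), integer(1))
  list(sets = sets, deg = deg, universe = ids,
       truth = list(deg_genes = ids[is_deg], hits = hits, shared = shared,
                    set_size = set_size))
}
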