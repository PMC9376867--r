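#' Cluster genomes into mOTUs from pairwise ANI
#'
#' Groups genomes into metagenomic operational taxonomic units (mOTUs,
#' an operational species definition): connected components of the
#' undirected graph whose edges are genome pairs with average
#' nucleotide identity at or above the threshold (default 95%).
#' Pairs reported in both orientations with different values are
#' reconciled by the maximum by default (`reconcile = "min"` demands
#' reciprocal support instead). Self-comparisons are ignored with a
#' warning. Singletons are returned as their own clusters.
#'
#' When a CheckM-style quality table is supplied, genomes can be
#' pre-filtered on completeness and contamination before clustering.
#'
#' @param edges a data frame with columns `genome_a`, `genome_b`, `ani`
#'   (percent in (0, 100]), e.g. from [read_ani()].
#' @param threshold minimum ANI (percent) for an edge.
#' @param genomes optional character vector of all genomes to cluster;
#'   genomes mentioned in no (retained) edge become singletons.
#' @param reconcile how to combine asymmetric orientations of a pair.
#' @param checkm optional quality data frame from [read_checkm()] used
#'   for pre-filtering.
#' @param min_completeness,max_contamination pre-filter bounds on the
#'   percent scale, applied when `checkm` is given.
#' @return an object of class `motu_clusters`: a named list of genome
#'   id vectors, ordered by decreasing size then by lexicographically
#'   smallest member; members sorted within each cluster.
#' @examples
#' ani <- data.frame(genome_a = c("A", "B", "C"),
#'                   genome_b = c("B", "C", "D"),
#'                   ani = c(96, 97, 80))
#' motu_components(ani, threshold = 95)
#' @export
motu_components <- function(edges, threshold = 95, genomes = NULL,
                            reconcile = c("max", "min"),
                            checkm = NULL, min_completeness = 30,
                            max_contamination = 10) {
  reconcile <- match.arg(reconcile)
  stopifnot(is.data.frame(edges),
            all(c("genome_a", "genome_b", "ani") %in% names(edges)))
  bad <- which(!is.finite(edges$ani) | edges$ani <= 0 | edges$ani > 100)
  if (length(bad))
    stop("ANI outside (0, 100] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  self <- edges$genome_a == edges$genome_b
  if (any(self)) {
    warning(sum(self), " self-comparison(s) ignored", call. = FALSE)
    edges <- edges[!self, , drop = FALSE]
  }
  universe <- sort(unique(c(edges$genome_a, edges$genome_b, genomes)))
  if (!is.null(checkm)) {
    drop <- checkm$genome_id[checkm$completeness * 100 < min_completeness]
    if (!is.null(checkm$contamination))
      drop <- union(drop,
                    checkm$genome_id[checkm$contamination * 100 >
                                       max_contamination])
    universe <- setdiff(universe, drop)
    keep <- edges$genome_a %in% universe & edges$genome_b %in% universe
    edges <- edges[keep, , drop = FALSE]
  }
  if (length(universe) == 0) stop("no genomes to cluster", call. = FALSE)

  # reconcile orientations, then threshold
  key <- ifelse(edges$genome_a < edges$genome_b,
                paste(edges$genome_a, edges$genome_b, sep = "\r"),
                paste(edges$genome_b, edges$genome_a, sep = "\r"))
  agg_fun <- if (reconcile == "max") max else min
  keep_pairs <- if (nrow(edges) > 0) {
    ani <- tapply(edges$ani, key, agg_fun)
    names(ani)[ani >= threshold]
  } else character()
  ab <- do.call(rbind, strsplit(keep_pairs, "\r", fixed = TRUE))

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(universe), name = universe)
  if (!is.null(ab) && nrow(ab) > 0)
    g <- igraph::add_edges(g, t(ab))
  comp <- igraph::components(g)
  members <- split(universe, comp$membership)
  members <- lapply(members, sort)
  leader <- vapply(members, `[[`, "", 1)
  o <- order(-lengths(members), leader)
  members <- members[o]
  names(members) <- sprintf("motu_%03d", seq_along(members))
  structure(members, class = "motu_clusters")
}

#' @export
print.motu_clusters <- function(x, ...) {
  cat("mOTU clustering:", length(x), "cluster(s) over",
      sum(lengths(x)), "genomes\n")
  n <- min(length(x), 8)
  for (i in seq_len(n))
    cat("  ", names(x)[i], " (", lengths(x)[i], "): ",
        paste(utils::head(x[[i]], 6), collapse = ", "),
        if (lengths(x)[i] > 6) ", ..." else "", "\n", sep = "")
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}
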