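# Cluster/singleton assignment from ANI (primary evidence) with optional
# shared-gene-content corroboration. Clusters are connected components of
# the thresholded genome graph, mirroring the single-linkage convention of
# the actinobacteriophage literature; components of size 1 are singletons.

#' Parameters for cluster assignment
#'
#' An edge joins two genomes when symmetrized ANI >= `t_ani` AND aligned
#' fraction >= `t_frac`; when `t_gene` is non-`NULL`, a shared-gene fraction
#' >= `t_gene` also creates a (corroborating) edge. ANI is the primary
#' evidence: substantial gene sharing without genome-wide nucleotide
#' identity (the hallmark of related-but-separate clusters) must not merge
#' clusters, so `t_gene` is disabled by default.
#'
#' @param t_ani Minimum symmetrized ANI (0-1) for an edge.
#' @param t_frac Minimum symmetrized aligned fraction (0-1).
#' @param t_gene Optional minimum symmetric shared-gene fraction; `NULL`
#'   disables gene-content edges.
#' @param label_scheme Ordered cluster labels; defaults to AK, AL, AM, ...
#'   (continuing the lettering already in use for actinobacteriophage
#'   clusters). Purely cosmetic.
#' @param subdivision_floor Report-only floor on intra-cluster ANI used by
#'   [intra_cluster_ani_summary()].
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(t_ani = 0.60, t_frac = 0.50, t_gene = NULL,
                              label_scheme = default_cluster_labels(),
                              subdivision_floor = 0.70) {
  stopifnot(t_ani >= 0, t_ani <= 1, t_frac >= 0, t_frac <= 1)
  if (!is.null(t_gene)) stopifnot(t_gene >= 0, t_gene <= 1)
  structure(list(t_ani = t_ani, t_frac = t_frac, t_gene = t_gene,
                 label_scheme = label_scheme,
                 subdivision_floor = subdivision_floor),
            class = "clustering_params")
}

#' Default cluster label sequence (AK, AL, ..., AZ, BA, BB, ...)
#' @return Character vector of labels.
#' @export
default_cluster_labels <- function() {
  two <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  two[which(two == "AK"):length(two)]
}

#' Directional and symmetric shared-gene fraction between two genomes
#'
#' The fraction of `a`'s genes whose pham also contains at least one gene of
#' `b` (`a_to_b`), the converse, and their mean. Requires the pham table to
#' cover both genomes.
#'
#' @param a,b Genome ids (or `genome` objects).
#' @param phams A `pham_table`.
#' @return List with `a_to_b`, `b_to_a`, `mean`.
#' @export
shared_gene_fraction <- function(a, b, phams) {
  stopifnot(inherits(phams, "pham_table"))
  ida <- if (inherits(a, "genome")) a$id else as.character(a)
  idb <- if (inherits(b, "genome")) b$id else as.character(b)
  mem <- phams$membership
  pa <- mem$pham_id[mem$phage_id == ida]
  pb <- mem$pham_id[mem$phage_id == idb]
  if (!length(pa) || !length(pb)) {
    stop("shared_gene_fraction undefined: genome with no genes in pham table (",
         if (!length(pa)) ida else idb, ")")
  }
  ab <- mean(pa %in% pb)
  ba <- mean(pb %in% pa)
  list(a_to_b = ab, b_to_a = ba, mean = (ab + ba) / 2)
}

#' Assign genomes to clusters and singletons
#'
#' Builds the genome graph under the thresholds in `params` and labels its
#' connected components: components with >= 2 members become clusters
#' (labels assigned by decreasing size, ties broken by the lexicographically
#' smallest member id), size-1 components are singletons.
#'
#' @param genomes A list of `genome` objects, or a character vector of
#'   genome ids matching the ANI matrix.
#' @param ani An `ani_matrix` from [ani_matrix()].
#' @param phams Optional `pham_table`; required when `params$t_gene` is set.
#' @param params A [clustering_params()] object.
#' @return An object of class `cluster_assignment`: list with `assignment`
#'   (data.frame `genome_id`, `cluster`; `"SINGLETON"` for singletons),
#'   `clusters` (named list label -> member ids), `singletons`, `evidence`
#'   (per-pair ani / aligned fraction / shared-gene fraction) and `params`.
#' @export
assign_clusters <- function(genomes, ani, phams = NULL,
                            params = clustering_params()) {
  ids <- if (is.character(genomes)) genomes else names(.as_genome_list(genomes))
  stopifnot(inherits(ani, "ani_matrix"))
  if (!all(ids %in% rownames(ani$ani))) {
    stop("ANI matrix does not cover all genomes")
  }
  use_gene <- !is.null(params$t_gene)
  if (use_gene && is.null(phams)) {
    stop("t_gene is set but no pham table was supplied")
  }
  n <- length(ids)
  pairs <- if (n >= 2L) t(combn(ids, 2L)) else matrix(character(), ncol = 2L)
  ev <- data.frame(a = pairs[, 1L], b = pairs[, 2L], stringsAsFactors = FALSE)
  ev$ani <- ani$ani[pairs]
  ev$aligned_fraction <- ani$aligned_fraction[pairs]
  ev$shared_gene_fraction <- NA_real_
  if (use_gene && nrow(ev)) {
    ev$shared_gene_fraction <- vapply(seq_len(nrow(ev)), function(k) {
      shared_gene_fraction(ev$a[k], ev$b[k], phams)$mean
    }, 0)
  }
  edge <- ev$ani >= params$t_ani & ev$aligned_fraction >= params$t_frac
  if (use_gene) {
    edge <- edge | (!is.na(ev$shared_gene_fraction) &
                      ev$shared_gene_fraction >= params$t_gene)
  }
  ev$edge <- edge
  g <- igraph::graph_from_data_frame(ev[edge, c("a", "b"), drop = FALSE],
                                     directed = FALSE, vertices = ids)
  comp <- igraph::components(g)
  members <- split(ids, comp$membership[ids])
  is_cluster <- lengths(members) >= 2L
  clusters <- members[is_cluster]
  singletons <- unlist(members[!is_cluster], use.names = FALSE)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(m) sort(m)[1], ""))
  clusters <- clusters[ord]
  if (length(clusters) > length(params$label_scheme)) {
    stop("label scheme exhausted: ", length(clusters), " clusters")
  }
  names(clusters) <- params$label_scheme[seq_along(clusters)]
  lab <- setNames(rep("SINGLETON", n), ids)
  for (cl in names(clusters)) lab[clusters[[cl]]] <- cl
  structure(list(
    assignment = data.frame(genome_id = ids, cluster = unname(lab[ids]),
                            stringsAsFactors = FALSE),
    clusters = clusters, singletons = sort(singletons %||% character()),
    evidence = ev, params = params
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d genomes: %d clusters, %d singletons\n",
              nrow(x$assignment), length(x$clusters), length(x$singletons)))
  for (cl in names(x$clusters)) {
    cat(sprintf("  %s (%d): %s\n", cl, length(x$clusters[[cl]]),
                paste(x$clusters[[cl]], collapse = ", ")))
  }
  if (length(x$singletons)) {
    cat("  singletons:", paste(x$singletons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Intra-cluster ANI summary
#'
#' Minimum, mean and maximum symmetrized ANI over all intra-cluster pairs,
#' with a report-only subdivision flag raised when the minimum falls below
#' the configured floor.
#'
#' @param members Character vector of cluster member ids (>= 2), or a
#'   cluster label plus an `assignment` to resolve it from.
#' @param ani An `ani_matrix`.
#' @param assignment Optional `cluster_assignment` when `members` is a label.
#' @param floor Subdivision floor; defaults to the assignment's parameter or
#'   0.70.
#' @return List with `min`, `mean`, `max`, `n_pairs`,
#'   `subdivision_flag`.
#' @export
intra_cluster_ani_summary <- function(members, ani, assignment = NULL,
                                      floor = NULL) {
  stopifnot(inherits(ani, "ani_matrix"))
  if (length(members) == 1L && !is.null(assignment)) {
    members <- assignment$clusters[[members]]
  }
  if (length(members) < 2L) stop("cluster must have >= 2 members")
  if (is.null(floor)) {
    floor <- if (!is.null(assignment)) assignment$params$subdivision_floor else 0.70
  }
  pairs <- t(combn(members, 2L))
  v <- ani$ani[pairs]
  list(min = min(v), mean = mean(v), max = max(v), n_pairs = length(v),
       subdivision_flag = min(v) < floor)
}

#' Write a cluster assignment as TSV
#'
#' Columns: `genome_id`, `cluster`, `n_members` (1 for singletons).
#'
#' @param assignment A `cluster_assignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters_tsv <- function(assignment, path) {
  df <- assignment$assignment
  sizes <- c(lengths(assignment$clusters),
             setNames(rep(1L, length(assignment$singletons)),
                      assignment$singletons))
  df$n_members <- ifelse(df$cluster == "SINGLETON", 1L,
                         as.integer(sizes[df$cluster]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
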