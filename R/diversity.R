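# Per-cluster diversity statistics: cluster-identifier phams, orpham
# percentages, inter-cluster and cross-host pham sharing. All percentages
# use the cluster's pham universe (distinct phams across its members) as
# denominator.

# pham universe of a set of genomes
.pham_universe <- function(genome_ids, phams) {
  mem <- phams$membership
  sort(unique(mem$pham_id[mem$phage_id %in% genome_ids]))
}

.resolve_cluster <- function(cluster, assignment) {
  if (length(cluster) == 1L && cluster %in% names(assignment$clusters)) {
    return(list(label = cluster, members = assignment$clusters[[cluster]]))
  }
  if (length(cluster) == 1L && cluster %in% assignment$singletons) {
    return(list(label = cluster, members = cluster))
  }
  list(label = NA_character_, members = cluster)
}

#' Cluster-identifier phams
#'
#' Phams present in every member of the cluster and absent from all phages
#' of other clusters and singletons in the study set. Not computed for
#' singletons (the notion requires >= 2 members); a singleton input yields
#' `computed = FALSE` with `percent = NA`.
#'
#' @param cluster A cluster label (resolved via `assignment`) or character
#'   vector of member genome ids.
#' @param assignment A `cluster_assignment` covering the study set.
#' @param phams A `pham_table`.
#' @return List with `phams` (ids), `percent` (of the cluster pham
#'   universe), `universe_size`, `computed`.
#' @export
cluster_identifier_phams <- function(cluster, assignment, phams) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(phams, "pham_table"))
  res <- .resolve_cluster(cluster, assignment)
  members <- res$members
  if (length(members) < 2L) {
    return(list(phams = character(0), percent = NA_real_,
                universe_size = length(.pham_universe(members, phams)),
                computed = FALSE))
  }
  mem <- phams$membership
  universe <- .pham_universe(members, phams)
  in_all <- vapply(universe, function(p) {
    carriers <- unique(mem$phage_id[mem$pham_id == p])
    all(members %in% carriers)
  }, TRUE)
  others <- setdiff(assignment$assignment$genome_id, members)
  outside <- .pham_universe(others, phams)
  idp <- universe[in_all & !(universe %in% outside)]
  list(phams = idp, percent = 100 * length(idp) / length(universe),
       universe_size = length(universe), computed = TRUE)
}

#' Orpham percentage of a cluster or genome
#'
#' `100 * (#orphams among the scope's phams) / (scope pham universe)`.
#' See [orphams()] for the orpham definition; without an attached external
#' reference it reduces to internal singleton phams, and the result records
#' which definition applied.
#'
#' @param scope A cluster label, singleton id, or character vector of genome
#'   ids.
#' @param phams A `pham_table`.
#' @param assignment Optional `cluster_assignment` to resolve labels.
#' @return List with `percent`, `orphams`, `universe_size`, `definition`.
#' @export
orpham_percent <- function(scope, phams, assignment = NULL) {
  stopifnot(inherits(phams, "pham_table"))
  members <- if (!is.null(assignment)) {
    .resolve_cluster(scope, assignment)$members
  } else scope
  universe <- .pham_universe(members, phams)
  orph <- intersect(orphams(phams), universe)
  list(percent = if (length(universe)) 100 * length(orph) / length(universe) else 0,
       orphams = orph, universe_size = length(universe),
       definition = if (phams$external_attached) {
         "single internal gene, no external members"
       } else "single internal gene (no external reference attached)")
}

#' Inter-cluster shared-pham percentage
#'
#' The proportion of a cluster's phams that are also present in at least one
#' phage of another cluster or singleton of the study set.
#'
#' @inheritParams cluster_identifier_phams
#' @return List with `percent`, `phams`, `universe_size`.
#' @export
intercluster_shared_percent <- function(cluster, assignment, phams) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(phams, "pham_table"))
  res <- .resolve_cluster(cluster, assignment)
  members <- res$members
  universe <- .pham_universe(members, phams)
  others <- setdiff(assignment$assignment$genome_id, members)
  outside <- .pham_universe(others, phams)
  shared <- intersect(universe, outside)
  list(percent = if (length(universe)) 100 * length(shared) / length(universe) else 0,
       phams = shared, universe_size = length(universe))
}

#' Cross-host (external) shared-pham percentage
#'
#' The proportion of a cluster's phams that have at least one member from
#' the attached external reference set (phages of other host genera).
#'
#' @inheritParams cluster_identifier_phams
#' @return List with `percent`, `phams`, `universe_size`.
#' @export
external_shared_percent <- function(cluster, assignment, phams) {
  stopifnot(inherits(phams, "pham_table"))
  if (!phams$external_attached) {
    stop("no external reference set attached; see attach_external()")
  }
  res <- .resolve_cluster(cluster, assignment)
  universe <- .pham_universe(res$members, phams)
  shared <- universe[phams$external_members[universe] >= 1L]
  list(percent = if (length(universe)) 100 * length(shared) / length(universe) else 0,
       phams = shared, universe_size = length(universe))
}

#' Pham sharing between all cluster pairs
#'
#' Symmetric counts of phams with members in both clusters (singletons
#' included as their own units), plus fractions relative to each unit's
#' pham universe.
#'
#' @param assignment A `cluster_assignment`.
#' @param phams A `pham_table`.
#' @return List with `counts` (symmetric matrix; diagonal = universe
#'   sizes) and `fraction_of_row` (counts divided by the row unit's
#'   universe size).
#' @export
pairwise_cluster_sharing_table <- function(assignment, phams) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(phams, "pham_table"))
  units <- c(assignment$clusters,
             setNames(as.list(assignment$singletons), assignment$singletons))
  labs <- names(units)
  universes <- lapply(units, .pham_universe, phams = phams)
  n <- length(labs)
  counts <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    counts[i, i] <- length(universes[[i]])
    if (i < n) for (j in (i + 1L):n) {
      k <- length(intersect(universes[[i]], universes[[j]]))
      counts[i, j] <- counts[j, i] <- k
    }
  }
  frac <- counts / pmax(1L, diag(counts))
  list(counts = counts, fraction_of_row = frac)
}

#' Per-cluster diversity report
#'
#' One row per cluster and singleton: member count, pham universe size,
#' percent cluster-identifier phams (NA for singletons), percent orphams,
#' percent phams shared with another cluster of the study set, and percent
#' shared with the external reference (NA when none is attached).
#'
#' @param assignment A `cluster_assignment`.
#' @param phams A `pham_table`.
#' @return A data.frame of class `diversity_report`.
#' @export
diversity_report <- function(assignment, phams) {
  units <- c(names(assignment$clusters), assignment$singletons)
  rows <- lapply(units, function(u) {
    res <- .resolve_cluster(u, assignment)
    idp <- cluster_identifier_phams(u, assignment, phams)
    data.frame(
      cluster = u,
      n_members = length(res$members),
      n_phams = idp$universe_size,
      pct_identifier = if (idp$computed) idp$percent else NA_real_,
      pct_orpham = orpham_percent(u, phams, assignment)$percent,
      pct_shared_other_cluster = intercluster_shared_percent(u, assignment, phams)$percent,
      pct_shared_other_host = if (phams$external_attached) {
        external_shared_percent(u, assignment, phams)$percent
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_report", "data.frame")
  out
}

#' Bar-chart display of a diversity report
#'
#' Grouped bars per cluster: identifier phams, orphams, inter-cluster
#' sharing, and cross-host sharing (when available).
#'
#' @param x A `diversity_report`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.diversity_report <- function(x, ...) {
  cols <- c(pct_identifier = "red3", pct_orpham = "royalblue",
            pct_shared_other_cluster = "gold",
            pct_shared_other_host = "forestgreen")
  keep <- names(cols)[colSums(!is.na(x[names(cols)])) > 0]
  m <- t(as.matrix(x[, keep, drop = FALSE]))
  colnames(m) <- sprintf("%s (%d)", x$cluster, x$n_members)
  barplot(m, beside = TRUE, col = cols[keep], ylab = "% of cluster phams",
          las = 2, ...)
  legend("topright", bty = "n", fill = cols[keep],
         legend = c(pct_identifier = "cluster-identifier",
                    pct_orpham = "orphams",
                    pct_shared_other_cluster = "shared, other cluster",
                    pct_shared_other_host = "shared, other host")[keep])
  invisible(x)
}
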