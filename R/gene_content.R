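# Gene-content comparison: pham presence/absence matrix, binary distances,
# NEXUS export for split-network display, and neighbor-joining trees.

#' Pham presence/absence matrix
#'
#' Rows are genomes, columns are pham ids (sorted); a cell is 1 iff the
#' genome carries at least one gene of that pham.
#'
#' @param phams A `pham_table`.
#' @param genomes Optional character vector (or list of `genome` objects)
#'   fixing the row set and order; every requested genome must appear in the
#'   pham table. Default: all genomes in the table, sorted.
#' @return A binary integer matrix with genome row names and pham column
#'   names.
#' @export
presence_matrix <- function(phams, genomes = NULL) {
  stopifnot(inherits(phams, "pham_table"))
  mem <- phams$membership
  ids <- if (is.null(genomes)) {
    sort(unique(mem$phage_id))
  } else if (is.character(genomes)) genomes else names(.as_genome_list(genomes))
  missing <- setdiff(ids, mem$phage_id)
  if (length(missing)) {
    stop("genome(s) absent from pham table: ", paste(missing, collapse = ", "))
  }
  pham_ids <- sort(names(phams$phams))
  m <- matrix(0L, length(ids), length(pham_ids),
              dimnames = list(ids, pham_ids))
  sub <- mem[mem$phage_id %in% ids, c("phage_id", "pham_id")]
  m[cbind(sub$phage_id, sub$pham_id)] <- 1L
  m
}

#' Gene-content distances between genomes
#'
#' Jaccard distance `1 - |P_a intersect P_b| / |P_a union P_b|` over pham
#' sets (the default; computed with [stats::dist()]'s binary method), or the
#' `"shared-fraction"` alternative `1 - mean(directional shared fractions)`.
#'
#' @param m A presence/absence matrix from [presence_matrix()].
#' @param metric `"jaccard"` or `"shared-fraction"`.
#' @return A [stats::dist] object with a `metric` attribute.
#' @export
gene_content_distance <- function(m, metric = c("jaccard", "shared-fraction")) {
  metric <- match.arg(metric)
  if (nrow(m) < 2L) stop("need at least two genomes")
  if (any(rowSums(m) == 0L)) {
    stop("gene-content distance undefined: genome(s) with empty pham set: ",
         paste(rownames(m)[rowSums(m) == 0L], collapse = ", "))
  }
  d <- if (metric == "jaccard") {
    dist(m, method = "binary")
  } else {
    n <- nrow(m)
    out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        inter <- sum(m[i, ] & m[j, ])
        s_ij <- inter / sum(m[i, ]); s_ji <- inter / sum(m[j, ])
        out[i, j] <- out[j, i] <- 1 - (s_ij + s_ji) / 2
      }
    }
    as.dist(out)
  }
  attr(d, "metric") <- metric
  d
}

#' Neighbor-joining tree from gene-content distances
#'
#' Canonical neighbor joining (via [ape::nj()]); negative branch lengths,
#' an artifact of NJ on non-additive distances, are clamped to zero.
#'
#' @param d A [stats::dist] object or symmetric matrix.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Export a presence/absence matrix or distance matrix as NEXUS
#'
#' A binary matrix becomes a `CHARACTERS` block (`DATATYPE=STANDARD`,
#' `SYMBOLS="01"`); a `dist` or square numeric matrix becomes a `DISTANCES`
#' block. Both load in standard split-network software, which applies its
#' own character-to-distance transform to the binary block.
#'
#' @param x Binary matrix (genomes x phams) or `dist`/square matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_nexus <- function(x, path) {
  is_dist <- inherits(x, "dist") ||
    (is.matrix(x) && nrow(x) == ncol(x) && !is.null(rownames(x)) &&
       identical(rownames(x), colnames(x)) && !all(x %in% c(0L, 1L)))
  taxa <- if (inherits(x, "dist")) attr(x, "Labels") else rownames(x)
  if (is.null(taxa) || any(!nzchar(taxa))) stop("export_nexus: unnamed taxa")
  if (anyDuplicated(taxa)) {
    stop("export_nexus: taxa name collision: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  qt <- function(s) paste0("'", gsub("'", "_", s), "'")
  con <- file(path, "wt"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#NEXUS")
  w("")
  w("BEGIN TAXA;")
  w(sprintf("  DIMENSIONS NTAX=%d;", length(taxa)))
  w(paste0("  TAXLABELS ", paste(qt(taxa), collapse = " "), ";"))
  w("END;")
  w("")
  if (is_dist) {
    m <- as.matrix(x)
    w("BEGIN DISTANCES;")
    w("  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;")
    w("  MATRIX")
    for (i in seq_along(taxa)) {
      w(sprintf("    %s %s", qt(taxa[i]),
                paste(format(m[i, ], digits = 10, trim = TRUE), collapse = " ")))
    }
    w("  ;")
    w("END;")
  } else {
    w("BEGIN CHARACTERS;")
    w(sprintf("  DIMENSIONS NCHAR=%d;", ncol(x)))
    w('  FORMAT DATATYPE=STANDARD SYMBOLS="01" MISSING=? GAP=-;')
    w("  MATRIX")
    for (i in seq_along(taxa)) {
      w(sprintf("    %s %s", qt(taxa[i]), paste(x[i, ], collapse = "")))
    }
    w("  ;")
    w("END;")
  }
  invisible(path)
}

#' Presence/absence matrix over one representative genome per cluster
#'
#' By default the representative of each cluster is its largest genome;
#' singletons represent themselves. Explicit representatives can be supplied
#' as a named character vector (cluster label -> genome id).
#'
#' @param assignment A `cluster_assignment`.
#' @param phams A `pham_table`.
#' @param genomes List of `genome` objects (needed to rank by length unless
#'   `representatives` overrides every cluster).
#' @param representatives Optional named character vector of overrides.
#' @return A presence/absence matrix over the chosen genomes.
#' @export
representative_matrix <- function(assignment, phams, genomes = NULL,
                                  representatives = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  reps <- character(0)
  for (cl in names(assignment$clusters)) {
    if (!is.null(representatives) && cl %in% names(representatives)) {
      rep_id <- representatives[[cl]]
      if (!rep_id %in% assignment$clusters[[cl]]) {
        stop("representative ", rep_id, " is not a member of cluster ", cl)
      }
    } else {
      if (is.null(genomes)) {
        stop("genomes needed to pick representatives by length")
      }
      gl <- .as_genome_list(genomes)
      mem <- assignment$clusters[[cl]]
      lens <- vapply(gl[mem], genome_length, 0L)
      rep_id <- mem[order(-lens, mem)][1]
    }
    reps[cl] <- rep_id
  }
  presence_matrix(phams, c(unname(reps), assignment$singletons))
}
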