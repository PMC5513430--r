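# Pham construction: all-vs-all protein similarity + single-linkage
# clustering. A pham ("phamily") is a connected component of the graph whose
# edges are protein pairs passing both a percent-identity and a coverage
# threshold under local (Smith-Waterman) alignment.

#' Parameters for pham construction
#'
#' The defaults follow the Phamerator-lineage convention: an edge between
#' two proteins requires a local alignment with percent identity >= 32.5
#' over aligned columns and coverage >= 0.5 of the shorter protein.
#' Local alignment (BLOSUM62, gap open 11, extend 1) is used because phage
#' proteins share domains amid mosaicism; the coverage guard prevents
#' domain-only hits from chaining everything into one pham.
#'
#' @param min_identity Minimum percent identity (0-100) for an edge.
#' @param min_coverage Minimum coverage (0-1) of the shorter protein.
#' @param gap_opening,gap_extension Gap penalties (positive, Biostrings
#'   convention).
#' @param substitution_matrix Name of the substitution matrix.
#' @param prefilter Use the shared k-mer prefilter to skip hopeless pairs.
#'   Off by default: component structure is then exactly the transitive
#'   closure of the thresholded all-vs-all matrix. Turning it on speeds up
#'   large corpora considerably; pairs passing the edge thresholds share
#'   k-mers at far higher rates than the floor, and the test suite verifies
#'   equality with unfiltered runs on simulated collections, but an exact
#'   k-mer filter can in principle drop a borderline pair (~33% identity
#'   proteins need not share any exact 4-mer).
#' @param prefilter_k,prefilter_min k-mer length and minimum shared distinct
#'   k-mers for a pair to be aligned when `prefilter` is on.
#' @return A list of class `pham_params`.
#' @export
pham_params <- function(min_identity = 32.5, min_coverage = 0.5,
                        gap_opening = 11, gap_extension = 1,
                        substitution_matrix = "BLOSUM62",
                        prefilter = FALSE, prefilter_k = 4L,
                        prefilter_min = 1L) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 substitution_matrix = substitution_matrix,
                 prefilter = prefilter, prefilter_k = as.integer(prefilter_k),
                 prefilter_min = as.integer(prefilter_min)),
            class = "pham_params")
}

.matrix_cache <- new.env(parent = emptyenv())

.subst_matrix <- function(name) {
  if (!exists(name, envir = .matrix_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .matrix_cache)
  }
  get(name, envir = .matrix_cache)
}

#' Pairwise protein similarity
#'
#' Local alignment of two amino-acid sequences. Percent identity is computed
#' over aligned columns (gap columns included); coverage is the aligned span
#' on the shorter protein divided by the shorter protein's length, so a
#' full-length containment scores coverage 1.
#'
#' @param a,b Amino-acid strings, or single-row entries of the protein table
#'   from [collect_proteins()].
#' @param params A [pham_params()] object.
#' @param ids Optional character vector of length 2 with the two protein ids.
#' @return A one-row data.frame (`query_id`, `subject_id`,
#'   `percent_identity`, `coverage`, `score`) with ids in canonical
#'   (sorted) order.
#' @export
protein_pairwise <- function(a, b, params = pham_params(), ids = c("a", "b")) {
  a <- .as_aa(a); b <- .as_aa(b)
  if (!nzchar(a) || !nzchar(b)) stop("protein_pairwise: empty translation")
  hit <- .align_protein_batch(a, b, params)
  if (ids[1] > ids[2]) {  # canonical order; measures are symmetric
    ids <- rev(ids)
  }
  data.frame(query_id = ids[1], subject_id = ids[2],
             percent_identity = hit$identity, coverage = hit$coverage,
             score = hit$score, stringsAsFactors = FALSE)
}

.as_aa <- function(x) {
  if (is.list(x) || is.data.frame(x)) x <- x$translation
  toupper(as.character(x)[1])
}

# Elementwise local alignment of pattern/subject vectors; returns identity
# over aligned columns (PID1), coverage on the shorter sequence, and score.
.align_protein_pairs <- function(patterns, subjects, params) {
  mat <- .subst_matrix(params$substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAStringSet(subjects),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension
  )
  plen <- nchar(patterns); slen <- nchar(subjects)
  # aligned span measured on each sequence's own coordinates
  p_span <- abs(BiocGenerics::end(Biostrings::pattern(aln)) -
                  BiocGenerics::start(Biostrings::pattern(aln))) + 1L
  s_span <- abs(BiocGenerics::end(Biostrings::subject(aln)) -
                  BiocGenerics::start(Biostrings::subject(aln))) + 1L
  shorter <- pmin(plen, slen)
  span_on_shorter <- ifelse(plen <= slen, p_span, s_span)
  list(identity = Biostrings::pid(aln, type = "PID1"),
       coverage = pmin(1, span_on_shorter / shorter),
       score = Biostrings::score(aln))
}

.align_protein_batch <- function(patterns, subject, params) {
  .align_protein_pairs(patterns, rep(subject, length(patterns)), params)
}

# Candidate pairs sharing >= min_shared distinct k-mers, via a sparse
# protein-by-kmer incidence matrix.
.kmer_candidate_pairs <- function(translations, k, min_shared) {
  n <- length(translations)
  if (n < 2L) return(matrix(integer(), ncol = 2L))
  kmers <- lapply(translations, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  vocab <- unique(unlist(kmers, use.names = FALSE))
  if (!length(vocab)) return(matrix(integer(), ncol = 2L))
  i <- rep.int(seq_len(n), lengths(kmers))
  j <- match(unlist(kmers, use.names = FALSE), vocab)
  inc <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, length(vocab)))
  shared <- Matrix::tcrossprod(inc)
  shared <- methods::as(Matrix::triu(shared, k = 1L), "TsparseMatrix")
  keep <- shared@x >= min_shared
  cbind(shared@i[keep] + 1L, shared@j[keep] + 1L)
}

#' Group proteins into phams by single-linkage clustering
#'
#' Computes the thresholded all-vs-all similarity graph (see
#' [protein_pairwise()]) and takes its connected components as phams.
#' Pham ids are content-derived and deterministic: components are ordered by
#' decreasing size, ties broken by the lexicographically smallest member
#' protein id, then numbered `pham_0001`, `pham_0002`, ...
#'
#' @param proteins A data.frame with columns `protein_id`, `phage_id`,
#'   `translation` (see [collect_proteins()]).
#' @param params A [pham_params()] object.
#' @return An object of class `pham_table` with elements
#'   `membership` (data.frame `protein_id`, `phage_id`, `pham_id`),
#'   `phams` (named list pham id -> member protein ids),
#'   `external_members` (named integer, initialized to 0),
#'   `external_genera` (named list), `external_attached` (flag),
#'   `edges` (the passing similarity edges) and `params`.
#' @export
build_phams <- function(proteins, params = pham_params()) {
  proteins <- .check_protein_table(proteins)
  n <- nrow(proteins)
  cand <- if (isTRUE(params$prefilter)) {
    .kmer_candidate_pairs(proteins$translation, params$prefilter_k,
                          params$prefilter_min)
  } else {
    if (n >= 2L) t(combn(n, 2L)) else matrix(integer(), ncol = 2L)
  }
  edges <- .edge_table(proteins, cand, params)
  g <- igraph::graph_from_data_frame(
    edges[, c("query_id", "subject_id")], directed = FALSE,
    vertices = proteins$protein_id
  )
  comp <- igraph::components(g)
  members <- split(proteins$protein_id, comp$membership[proteins$protein_id])
  ord <- order(-lengths(members),
               vapply(members, function(m) sort(m)[1], ""))
  members <- members[ord]
  pham_ids <- sprintf("pham_%04d", seq_along(members))
  names(members) <- pham_ids
  p2p <- setNames(rep(pham_ids, lengths(members)),
                  unlist(members, use.names = FALSE))
  membership <- data.frame(protein_id = proteins$protein_id,
                           phage_id = proteins$phage_id,
                           pham_id = unname(p2p[proteins$protein_id]),
                           stringsAsFactors = FALSE)
  structure(list(membership = membership, phams = members,
                 external_members = setNames(integer(length(members)), pham_ids),
                 external_genera = setNames(vector("list", length(members)), pham_ids),
                 external_attached = FALSE,
                 edges = edges, params = params),
            class = "pham_table")
}

.check_protein_table <- function(proteins) {
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  need <- c("protein_id", "phage_id", "translation")
  miss <- setdiff(need, names(proteins))
  if (length(miss)) stop("protein table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(proteins) < 1L) stop("need at least one protein")
  if (anyDuplicated(proteins$protein_id)) stop("duplicate protein_id")
  if (any(!nzchar(proteins$translation))) stop("empty translation(s) in protein table")
  proteins
}

.empty_edges <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), coverage = numeric(),
             score = numeric(), stringsAsFactors = FALSE)
}

# Align candidate (i, j) index pairs (chunked elementwise batches) and keep
# those passing both thresholds.
.edge_table <- function(proteins, cand, params, chunk = 2000L) {
  if (!nrow(cand)) return(.empty_edges())
  out <- vector("list", 0L)
  for (off in seq(1L, nrow(cand), by = chunk)) {
    idx <- off:min(off + chunk - 1L, nrow(cand))
    ii <- cand[idx, 1L]; jj <- cand[idx, 2L]
    hit <- .align_protein_pairs(proteins$translation[ii],
                                proteins$translation[jj], params)
    keep <- hit$identity >= params$min_identity &
      hit$coverage >= params$min_coverage
    if (any(keep)) {
      qs <- proteins$protein_id[ii[keep]]
      ss <- proteins$protein_id[jj[keep]]
      swap <- qs > ss
      out[[length(out) + 1L]] <- data.frame(
        query_id = ifelse(swap, ss, qs), subject_id = ifelse(swap, qs, ss),
        percent_identity = hit$identity[keep], coverage = hit$coverage[keep],
        score = hit$score[keep], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(.empty_edges())
  edges <- do.call(rbind, out)
  edges <- edges[order(edges$query_id, edges$subject_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Construct a pham table directly from a membership assignment
#'
#' Constructor for a `pham_table` from a known partition, without any
#' alignment. Used to build ground-truth tables in simulations and tests and
#' to import partitions computed elsewhere.
#'
#' @param membership A data.frame with columns `protein_id`, `phage_id`,
#'   `pham_id` partitioning the proteins.
#' @param external_members Optional named integer vector (by pham id) of
#'   external reference members; phams absent from it get 0.
#' @param external_genera Optional named list (by pham id) of character
#'   vectors of external host genera.
#' @param params Parameter list to record.
#' @return A `pham_table`.
#' @export
pham_table <- function(membership, external_members = NULL,
                       external_genera = NULL, params = pham_params()) {
  membership <- as.data.frame(membership, stringsAsFactors = FALSE)
  need <- c("protein_id", "phage_id", "pham_id")
  miss <- setdiff(need, names(membership))
  if (length(miss)) stop("membership lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(membership$protein_id)) stop("duplicate protein_id in membership")
  phams <- split(membership$protein_id, membership$pham_id)
  ids <- names(phams)
  em <- setNames(integer(length(ids)), ids)
  if (!is.null(external_members)) {
    common <- intersect(names(external_members), ids)
    em[common] <- as.integer(external_members[common])
  }
  eg <- setNames(vector("list", length(ids)), ids)
  if (!is.null(external_genera)) {
    common <- intersect(names(external_genera), ids)
    eg[common] <- external_genera[common]
  }
  structure(list(membership = membership, phams = phams,
                 external_members = em, external_genera = eg,
                 external_attached = !is.null(external_members),
                 edges = .empty_edges(), params = params),
            class = "pham_table")
}

#' @export
print.pham_table <- function(x, ...) {
  sizes <- lengths(x$phams)
  cat(sprintf("<pham_table> %d proteins in %d phams (%d orphams)\n",
              nrow(x$membership), length(x$phams), length(orphams(x))))
  cat(sprintf("  sizes: max %d, median %d; external reference %s\n",
              max(sizes), as.integer(median(sizes)),
              if (x$external_attached) "attached" else "not attached"))
  invisible(x)
}

#' Attach an external reference protein set to a pham table
#'
#' Each external protein is assigned to an existing pham if at least one
#' member passes the same identity/coverage edge thresholds used to build
#' the table; external proteins matching no pham are ignored. When a protein
#' passes to members of more than one pham, the best-scoring pham is
#' credited. The partition of internal proteins is never changed.
#'
#' @param phams A `pham_table` from [build_phams()].
#' @param external A data.frame with columns `protein_id`, `genus`,
#'   `translation` (see [read_external_fasta()]).
#' @param proteins The internal protein table the phams were built from.
#' @return The updated `pham_table` with `external_members`,
#'   `external_genera` and `external_attached` set.
#' @export
attach_external <- function(phams, external, proteins) {
  stopifnot(inherits(phams, "pham_table"))
  external <- as.data.frame(external, stringsAsFactors = FALSE)
  proteins <- .check_protein_table(proteins)
  if (!setequal(proteins$protein_id, phams$membership$protein_id)) {
    stop("protein table does not match the pham table membership")
  }
  params <- phams$params
  phams$external_attached <- TRUE
  if (nrow(external) == 0L) return(phams)
  if (any(!nzchar(external$translation))) stop("empty external translation(s)")
  p2p <- setNames(phams$membership$pham_id, phams$membership$protein_id)
  n_int <- nrow(proteins)
  for (e in seq_len(nrow(external))) {
    cand <- if (isTRUE(params$prefilter)) {
      cc <- .kmer_candidate_pairs(
        c(proteins$translation, external$translation[e]),
        params$prefilter_k, params$prefilter_min
      )
      cc[cc[, 2L] == n_int + 1L, 1L]
    } else seq_len(n_int)
    if (!length(cand)) next
    hit <- .align_protein_batch(proteins$translation[cand],
                                external$translation[e], params)
    pass <- hit$identity >= params$min_identity &
      hit$coverage >= params$min_coverage
    if (!any(pass)) next
    best <- cand[pass][which.max(hit$score[pass])]
    pid <- unname(p2p[proteins$protein_id[best]])
    phams$external_members[pid] <- phams$external_members[pid] + 1L
    phams$external_genera[[pid]] <- unique(c(phams$external_genera[[pid]],
                                             external$genus[e]))
  }
  phams
}

#' Orphams of a pham table
#'
#' An orpham is a pham whose internal membership is a single gene from a
#' single phage and which has no external reference members. Without an
#' attached external set, the definition reduces to internal singleton
#' phams.
#'
#' @param phams A `pham_table`.
#' @return Character vector of orpham pham ids.
#' @export
orphams <- function(phams) {
  stopifnot(inherits(phams, "pham_table"))
  single <- names(phams$phams)[lengths(phams$phams) == 1L]
  single[phams$external_members[single] == 0L]
}

#' Write a pham table as TSV
#'
#' Columns: `protein_id`, `phage_id`, `pham_id`, `is_orpham`.
#'
#' @param phams A `pham_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pham_tsv <- function(phams, path) {
  orph <- orphams(phams)
  out <- phams$membership
  out$is_orpham <- out$pham_id %in% orph
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
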