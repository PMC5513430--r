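# Shared fixtures and independent oracles for the suite. Everything is
# generated in code under explicit seeds; no stored data files are needed
# beyond the printed reference table under inst/extdata.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# point-mutate a protein at the given per-residue rate
mutate_protein <- function(p, rate) {
  v <- strsplit(p, "")[[1]]
  hit <- runif(length(v)) < rate
  v[hit] <- sample(AA20, sum(hit), replace = TRUE)
  paste(v, collapse = "")
}

# canonical form of a partition: sorted list of sorted member vectors,
# so comparisons are invariant to labels and ordering
canon_partition <- function(members_by_group) {
  parts <- lapply(members_by_group, function(m) sort(as.character(m)))
  unname(parts[order(vapply(parts, `[[`, "", 1L))])
}

partition_of_pham_table <- function(pt) canon_partition(pt$phams)

# Independent single-linkage oracle: exhaustive thresholded all-vs-all
# similarity matrix, then transitive closure by boolean matrix products.
bf_pham_partition <- function(proteins, params = pham_params()) {
  n <- nrow(proteins)
  E <- diag(TRUE, n)
  if (n >= 2L) {
    pairs <- t(combn(n, 2L))
    hit <- phamlin:::.align_protein_pairs(proteins$translation[pairs[, 1]],
                                          proteins$translation[pairs[, 2]],
                                          params)
    pass <- hit$identity >= params$min_identity &
      hit$coverage >= params$min_coverage
    E[pairs[pass, , drop = FALSE]] <- TRUE
    E[pairs[pass, c(2, 1), drop = FALSE]] <- TRUE
    repeat {
      E2 <- E | ((E %*% E) > 0)
      if (identical(E2, E)) break
      E <- E2
    }
  }
  groups <- unique(apply(E, 1, function(r) paste(which(r), collapse = ",")))
  canon_partition(lapply(strsplit(groups, ","),
                         function(i) proteins$protein_id[as.integer(i)]))
}

# cluster labels with singletons made distinct, for ARI against truth
distinct_labels <- function(assignment) {
  lab <- assignment$assignment$cluster
  names(lab) <- assignment$assignment$genome_id
  s <- lab == "SINGLETON"
  lab[s] <- paste0("SGL_", names(lab)[s])
  lab
}

# fabricate an ani_matrix object from plain matrices (for graph-logic tests)
fake_ani_matrix <- function(ani, af = NULL) {
  if (is.null(af)) {
    af <- ani
    af[] <- 1
    diag(af) <- 1
  }
  structure(list(ani = ani, aligned_fraction = af, params = ani_params()),
            class = "ani_matrix")
}

# tiny annotated genome with explicit genes, for I/O tests
toy_genome <- function(id = "toy", seed = 1) {
  set.seed(seed)
  s <- rand_dna(600)
  genes <- data.frame(
    gene_id = c("g1", "g2"),
    start = c(30L, 300L), end = c(120L, 420L),
    strand = c("+", "-"),
    translation = c(rand_protein(29), rand_protein(39)),
    function_label = c("terminase", ""),
    stringsAsFactors = FALSE
  )
  genome(id, s, genes)
}
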