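# Synthetic mosaic pangenomes with planted ground truth.
#
# Proteins are simulated first (uniform residue draws with a mild dipeptide
# smoother), then reverse-translated with codon choice tilted to hit each
# unit's GC target -- phage GC tracks lineage, not host, so GC is a property
# of the planted cluster. Genomes are assembled as gene cassettes (CDS plus
# a downstream intergenic spacer inherited with the gene, so that intergenic
# DNA is homologous wherever the gene is shared). Within a cluster, each
# member derives from the ancestral cassettes by i.i.d. nucleotide
# substitution at rate/2 per lineage, making the expected *pairwise*
# divergence between members equal to the configured rate. Substitutions
# draw the replacement base from the GC-target composition and never create
# internal stop codons, so translations stay clean and GC stays on target.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for the synthetic pangenome generator
#'
#' Defaults describe a small study-like collection: 4 planted clusters of
#' 3-6 genomes plus 2 singletons, pairwise intra-cluster divergence 5%,
#' cluster GC targets spread over 0.45-0.68 (the range seen across real
#' phage collections), a low rate of pham sharing between clusters, and a
#' few percent orphams per genome.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param K Number of planted clusters.
#' @param sizes Genomes per cluster (length-`K` vector, or `NULL` to draw
#'   uniformly from `size_range`).
#' @param size_range Range sizes are drawn from when `sizes` is `NULL`.
#' @param n_singletons Number of singleton genomes.
#' @param genes_per_genome Integer range `c(lo, hi)` of genes per genome.
#' @param gene_length Lognormal parameters `c(meanlog, sdlog)` for protein
#'   length in amino acids (clipped to 50-1200).
#' @param core_fraction Fraction of the minimum gene count planted as core
#'   phams carried by every cluster member.
#' @param intra_cluster_site_mutation_rate Target pairwise per-site
#'   nucleotide divergence between cluster members (each lineage mutates at
#'   half this rate from the ancestor).
#' @param inter_cluster_share_rate Probability that a pham is copied into
#'   one other unit's accessory pool.
#' @param orpham_rate Fraction of each genome's genes planted as orphams
#'   (unique, unshared phams).
#' @param gc_target GC targets (0-1) per unit (clusters then singletons), or
#'   `NULL` for an even spread over 0.45-0.68.
#' @param intergenic_gap Integer range of intergenic spacer lengths (bp).
#' @param external_share_rate Probability that a pham gets a homologue in
#'   the external (other-host) reference protein set.
#' @param external_genera Host genus labels external proteins are drawn
#'   from.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, K = 4L, sizes = NULL, size_range = c(3L, 6L),
                       n_singletons = 2L, genes_per_genome = c(12L, 14L),
                       gene_length = c(meanlog = log(220), sdlog = 0.35),
                       core_fraction = 0.9,
                       intra_cluster_site_mutation_rate = 0.05,
                       inter_cluster_share_rate = 0.02,
                       orpham_rate = 0.08,
                       gc_target = NULL,
                       intergenic_gap = c(20L, 120L),
                       external_share_rate = 0,
                       external_genera = c("Mycobacterium", "Gordonia",
                                           "Rhodococcus", "Streptomyces")) {
  stopifnot(K >= 1L, n_singletons >= 0L,
            core_fraction >= 0, core_fraction <= 1,
            intra_cluster_site_mutation_rate >= 0,
            intra_cluster_site_mutation_rate <= 1,
            inter_cluster_share_rate >= 0, inter_cluster_share_rate <= 1,
            orpham_rate >= 0, orpham_rate <= 1,
            external_share_rate >= 0, external_share_rate <= 1,
            genes_per_genome[1] >= 1L,
            genes_per_genome[2] >= genes_per_genome[1])
  if (!is.null(sizes) && length(sizes) != K) {
    stop("sizes must have length K")
  }
  if (!is.null(sizes) && any(sizes < 2L)) {
    stop("cluster sizes must be >= 2 (use n_singletons for size-1 units)")
  }
  n_units <- K + n_singletons
  if (!is.null(gc_target)) {
    stopifnot(length(gc_target) == n_units, all(gc_target > 0 & gc_target < 1))
  }
  structure(list(seed = as.integer(seed), K = as.integer(K), sizes = sizes,
                 size_range = as.integer(size_range),
                 n_singletons = as.integer(n_singletons),
                 genes_per_genome = as.integer(genes_per_genome),
                 gene_length = gene_length, core_fraction = core_fraction,
                 intra_cluster_site_mutation_rate = intra_cluster_site_mutation_rate,
                 inter_cluster_share_rate = inter_cluster_share_rate,
                 orpham_rate = orpham_rate, gc_target = gc_target,
                 intergenic_gap = as.integer(intergenic_gap),
                 external_share_rate = external_share_rate,
                 external_genera = external_genera),
            class = "sim_config")
}

# --- sequence-level helpers -------------------------------------------------

.random_protein <- function(len, repeat_prob = 0.12, aa_prob = NULL) {
  draws <- sample(.AA20, len, replace = TRUE, prob = aa_prob)
  rep_prev <- runif(len) < repeat_prob
  rep_prev[1] <- FALSE
  res <- draws
  for (i in which(rep_prev)) res[i] <- res[i - 1L]
  paste(res, collapse = "")
}

# residue weights tilted toward GC-rich (or GC-poor) codon families, so
# that extreme GC targets stay reachable by codon choice alone afterwards;
# mirrors the compositional bias of real high-GC proteomes
.aa_weights <- function(gc, codon_tab, alpha = 1.5) {
  cbar <- vapply(.AA20, function(aa) mean(.codon_gc(codon_tab[[aa]])), 0)
  w <- (gc / (1 - gc))^(alpha * (cbar - 1.5))
  w / sum(w)
}

# aa -> sense codons for genetic code 11
.codon_table <- function() {
  gc11 <- Biostrings::getGeneticCode("11")
  split(names(gc11)[gc11 != "*"], gc11[gc11 != "*"])
}

.codon_gc <- function(codons) {
  vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")), 0L)
}

# tilt parameter t such that expected codon GC under weights
# t^gc * (1-t)^(3-gc) matches the target, for the given aa composition
.solve_gc_tilt <- function(aa_counts, target, codon_tab) {
  expected_gc <- function(t) {
    per_aa <- vapply(names(aa_counts), function(aa) {
      cods <- codon_tab[[aa]]
      gcc <- .codon_gc(cods)
      w <- t^gcc * (1 - t)^(3 - gcc)
      sum(w * gcc) / sum(w) / 3
    }, 0)
    sum(per_aa * aa_counts) / sum(aa_counts)
  }
  lo <- expected_gc(1e-3); hi <- expected_gc(1 - 1e-3)
  if (target <= lo) return(1e-3)
  if (target >= hi) return(1 - 1e-3)
  uniroot(function(t) expected_gc(t) - target, c(1e-3, 1 - 1e-3))$root
}

# reverse-translate a protein with GC-tilted codon choice; ATG start
.reverse_translate <- function(protein, tilt, codon_tab) {
  aas <- strsplit(protein, "")[[1]]
  cods <- character(length(aas))
  for (aa in unique(aas)) {
    cc <- codon_tab[[aa]]
    gcc <- .codon_gc(cc)
    w <- tilt^gcc * (1 - tilt)^(3 - gcc)
    at <- which(aas == aa)
    cods[at] <- if (length(cc) == 1L) cc else {
      sample(cc, length(at), replace = TRUE, prob = w)
    }
  }
  cods[1] <- "ATG"  # enforce a start codon (M is planted as first residue)
  paste(cods, collapse = "")
}

.random_dna <- function(len, gc) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# mutate a CDS at the given rate without creating internal stop codons
.mutate_cds_safe <- function(cds, rate, gc) {
  s <- .mutate_seq(cds, rate,
                   base_freq = c(A = (1 - gc) / 2, C = gc / 2,
                                 G = gc / 2, T = (1 - gc) / 2))
  n <- nchar(s) %/% 3L
  if (n > 1L) {
    starts <- seq(1L, by = 3L, length.out = n)
    cods <- substring(s, starts, starts + 2L)
    bad <- which(cods %in% c("TAA", "TAG", "TGA"))
    if (length(bad)) {
      cods[bad] <- paste0(substr(cods[bad], 1L, 2L), "C")  # -> Y/Y/C, never *
      s <- paste(cods, collapse = "")
    }
  }
  s
}

# --- generator --------------------------------------------------------------

#' Simulate a mosaic phage pangenome with planted truth
#'
#' Generates `K` clusters plus singletons under `config` (see
#' [sim_config()]) and returns the genomes alongside a truth table for every
#' planted structure. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_pangenome`:
#'   `genomes` (named list of [genome()] objects),
#'   `truth` (list: `genome_truth` data.frame genome/unit/type/gc_target;
#'   `gene_truth` data.frame protein_id/phage_id/gene_id/pham/is_orpham;
#'   `orphams` realized orpham labels -- planted phams whose realized
#'   membership is one gene in one genome with no external homologue;
#'   `planted_private_orphams` the member-private subset drawn at
#'   `orpham_rate`; `realized_intra_identity` named per
#'   cluster, Hamming identity of shared cassettes between member pairs),
#'   `external` (data.frame protein_id/genus/translation/pham, possibly
#'   empty) and `config`.
#' @export
simulate_pangenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  codon_tab <- .codon_table()
  K <- config$K
  sizes <- config$sizes
  if (is.null(sizes)) {
    sizes <- sample(config$size_range[1]:config$size_range[2], K, replace = TRUE)
  }
  n_units <- K + config$n_singletons
  gc <- config$gc_target
  if (is.null(gc)) gc <- seq(0.45, 0.68, length.out = max(n_units, 2L))[seq_len(n_units)]
  unit_labels <- c(if (K > 0) paste0("C", seq_len(K)),
                   if (config$n_singletons > 0) paste0("S", seq_len(config$n_singletons)))
  unit_sizes <- c(sizes, rep(1L, config$n_singletons))
  glo <- config$genes_per_genome[1]; ghi <- config$genes_per_genome[2]
  rate_half <- config$intra_cluster_site_mutation_rate / 2

  gene_len <- function() {
    max(50L, min(1200L, round(exp(rnorm(1, config$gene_length[["meanlog"]],
                                        config$gene_length[["sdlog"]])))))
  }

  # 1. per-unit pham pools (ancestral cassettes: protein, cds, spacer)
  units <- vector("list", n_units)
  names(units) <- unit_labels
  for (u in seq_len(n_units)) {
    n_core <- max(1L, round(config$core_fraction * glo))
    n_acc <- max(0L, ghi - n_core + 2L)
    n_pool <- n_core + n_acc
    aa_w <- .aa_weights(gc[u], codon_tab)
    prots <- vapply(seq_len(n_pool), function(p) {
      paste0("M", .random_protein(gene_len(), aa_prob = aa_w))
    }, "")
    # calibrate the codon tilt on the pooled composition of the unit's own
    # proteins (a per-protein probe is too noisy to hold the GC target)
    aa_counts <- table(factor(strsplit(paste(prots, collapse = ""), "")[[1]],
                              levels = .AA20))
    tilt <- .solve_gc_tilt(aa_counts[aa_counts > 0], gc[u], codon_tab)
    pool <- vector("list", n_pool)
    for (p in seq_len(n_pool)) {
      cds <- .reverse_translate(prots[p], tilt, codon_tab)
      spacer <- .random_dna(sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1L),
                            gc[u])
      pool[[p]] <- list(pham = sprintf("pham_%s_%03d", unit_labels[u], p),
                        cds = cds, spacer = spacer, core = p <= n_core,
                        shared_in = FALSE, origin = unit_labels[u],
                        strand = if (runif(1) < 0.8) "+" else "-")
    }
    units[[u]] <- list(pool = pool[sample.int(n_pool)], tilt = tilt, gc = gc[u],
                       lead = .random_dna(sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1L),
                                          gc[u]))
  }

  # 2. inter-unit sharing: copy phams into another unit's accessory pool
  if (config$inter_cluster_share_rate > 0 && n_units > 1L) {
    for (u in seq_len(n_units)) {
      for (cas in units[[u]]$pool) {
        if (cas$origin != unit_labels[u]) next  # don't re-share copies
        if (runif(1) < config$inter_cluster_share_rate) {
          v <- sample(setdiff(seq_len(n_units), u), 1L)
          shared <- cas
          shared$core <- FALSE
          shared$shared_in <- TRUE
          shared$cds <- .mutate_cds_safe(cas$cds, 0.05, units[[v]]$gc)
          units[[v]]$pool <- c(units[[v]]$pool, list(shared))
        }
      }
    }
  }

  # 3. assemble member genomes
  genomes <- list()
  genome_truth <- list(); gene_truth <- list()
  cassette_copies <- list()  # unit -> pham -> member cds copies (for realized ANI)
  anc_cds <- list()          # pham -> ancestral CDS (for external homologues)
  anc_gc <- list()           # pham -> GC of its unit of origin
  orpham_labels <- character(0)
  for (u in seq_len(n_units)) {
    pool <- units[[u]]$pool
    ugc <- units[[u]]$gc
    core_idx <- which(vapply(pool, `[[`, TRUE, "core"))
    acc_idx <- setdiff(seq_along(pool), core_idx)
    for (m in seq_len(unit_sizes[u])) {
      gid <- sprintf("%s_%02d", unit_labels[u], m)
      n_target <- sample(glo:ghi, 1L)
      n_orph <- round(config$orpham_rate * n_target)
      n_acc_want <- max(0L, n_target - length(core_idx) - n_orph)
      # accessory carriage is nested (prevalence-ordered): members take the
      # first n accessory phams, shared-in phams first -- so accessory
      # differences between members are few, as in real phage clusters
      acc_order <- acc_idx[order(!vapply(pool[acc_idx], `[[`, TRUE, "shared_in"),
                                 acc_idx)]
      acc_pick <- head(acc_order, min(n_acc_want, length(acc_order)))
      carry <- sort(c(core_idx, acc_pick))  # pool order preserved
      cassettes <- pool[carry]
      # member-private orphams
      for (o in seq_len(n_orph)) {
        lab <- sprintf("orph_%s_%02d", gid, o)
        prot <- paste0("M", .random_protein(gene_len(),
                                            aa_prob = .aa_weights(ugc, codon_tab)))
        cassettes <- c(cassettes, list(list(
          pham = lab,
          cds = .reverse_translate(prot, units[[u]]$tilt, codon_tab),
          spacer = .random_dna(sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1L), ugc),
          core = FALSE, origin = gid,
          strand = if (runif(1) < 0.8) "+" else "-"
        )))
        orpham_labels <- c(orpham_labels, lab)
      }
      lead <- if (rate_half > 0) {
        .mutate_seq(units[[u]]$lead, rate_half,
                    c(A = (1 - ugc) / 2, C = ugc / 2, G = ugc / 2, T = (1 - ugc) / 2))
      } else units[[u]]$lead
      seq_parts <- list(lead)
      genes <- list()
      cds_batch <- character(length(cassettes))
      pos <- nchar(lead)
      for (ci in seq_along(cassettes)) {
        cas <- cassettes[[ci]]
        cds <- .mutate_cds_safe(cas$cds, rate_half, ugc)
        cds_batch[ci] <- cds
        spacer <- if (rate_half > 0) {
          .mutate_seq(cas$spacer, rate_half,
                      c(A = (1 - ugc) / 2, C = ugc / 2, G = ugc / 2, T = (1 - ugc) / 2))
        } else cas$spacer
        strand <- cas$strand  # orientation is ancestral, shared by members
        placed <- if (strand == "+") cds else revcomp(cds)
        gene_id <- sprintf("g%03d", ci)
        genes[[ci]] <- data.frame(
          gene_id = gene_id, start = pos, end = pos + nchar(cds),
          strand = strand, translation = "",
          function_label = "", compound = FALSE, stringsAsFactors = FALSE
        )
        gene_truth[[length(gene_truth) + 1L]] <- data.frame(
          protein_id = paste(gid, gene_id, sep = "|"), phage_id = gid,
          gene_id = gene_id, pham = cas$pham,
          is_orpham = startsWith(cas$pham, "orph_"), stringsAsFactors = FALSE
        )
        if (unit_sizes[u] > 1L && !startsWith(cas$pham, "orph_")) {
          cassette_copies[[unit_labels[u]]][[cas$pham]] <-
            c(cassette_copies[[unit_labels[u]]][[cas$pham]], cds)
        }
        if (is.null(anc_cds[[cas$pham]])) {
          anc_cds[[cas$pham]] <- cas$cds
          anc_gc[[cas$pham]] <- ugc
        }
        seq_parts[[length(seq_parts) + 1L]] <- placed
        seq_parts[[length(seq_parts) + 1L]] <- spacer
        pos <- pos + nchar(placed) + nchar(spacer)
      }
      genes <- do.call(rbind, genes)
      genes$translation <- .translate_cds_batch(cds_batch)
      genomes[[gid]] <- genome(gid, paste(unlist(seq_parts), collapse = ""),
                               genes, source_format = "constructed")
      genome_truth[[length(genome_truth) + 1L]] <- data.frame(
        genome_id = gid, unit = unit_labels[u],
        type = if (unit_sizes[u] >= 2L) "cluster" else "singleton",
        gc_target = 100 * ugc, stringsAsFactors = FALSE
      )
    }
  }

  realized <- vapply(names(cassette_copies), function(cl) {
    per_pham <- vapply(cassette_copies[[cl]], function(copies) {
      if (length(copies) < 2L) return(NA_real_)
      pairs <- combn(length(copies), 2L)
      mean(vapply(seq_len(ncol(pairs)), function(k) {
        a <- strsplit(copies[[pairs[1, k]]], "")[[1]]
        b <- strsplit(copies[[pairs[2, k]]], "")[[1]]
        mean(a == b)
      }, 0))
    }, 0)
    mean(per_pham, na.rm = TRUE)
  }, 0)

  gene_truth <- do.call(rbind, gene_truth)

  # 4. external reference homologues, drawn over the realized phams so every
  # external protein has an internal counterpart to match
  external <- data.frame(protein_id = character(), genus = character(),
                         translation = character(), pham = character(),
                         stringsAsFactors = FALSE)
  if (config$external_share_rate > 0) {
    for (pham in sort(unique(gene_truth$pham))) {
      if (runif(1) < config$external_share_rate) {
        tr <- .translate_cds(.mutate_cds_safe(anc_cds[[pham]], 0.05,
                                              anc_gc[[pham]]))
        external <- rbind(external, data.frame(
          protein_id = paste0("ext_", pham),
          genus = sample(config$external_genera, 1L),
          translation = tr, pham = pham, stringsAsFactors = FALSE
        ))
      }
    }
  }
  # realized orphams: phams whose realized membership is a single gene in a
  # single genome with no external homologue (this includes accessory phams
  # that ended up carried by exactly one genome, not just the member-private
  # draws counted by orpham_rate)
  tab <- table(gene_truth$pham)
  realized_orphams <- sort(setdiff(names(tab)[tab == 1L], external$pham))

  structure(list(
    genomes = genomes,
    truth = list(
      genome_truth = do.call(rbind, genome_truth),
      gene_truth = gene_truth,
      orphams = realized_orphams,
      planted_private_orphams = sort(orpham_labels),
      realized_intra_identity = realized
    ),
    external = external,
    config = config
  ), class = "synthetic_pangenome")
}

#' @export
print.synthetic_pangenome <- function(x, ...) {
  gt <- x$truth$genome_truth
  cat(sprintf("<synthetic_pangenome> %d genomes (%d clusters, %d singletons), seed %d\n",
              nrow(gt), x$config$K, x$config$n_singletons, x$config$seed))
  cat(sprintf("  %d genes in %d planted phams (%d orphams); %d external proteins\n",
              nrow(x$truth$gene_truth), length(unique(x$truth$gene_truth$pham)),
              length(x$truth$orphams), nrow(x$external)))
  invisible(x)
}

#' Ground-truth pham table of a synthetic pangenome
#'
#' The planted partition as a `pham_table`, including external membership
#' counts, for truth-vs-pipeline comparisons.
#'
#' @param sim A `synthetic_pangenome`.
#' @return A `pham_table`.
#' @export
truth_pham_table <- function(sim) {
  gt <- sim$truth$gene_truth
  em <- table(sim$external$pham)
  pham_table(
    data.frame(protein_id = gt$protein_id, phage_id = gt$phage_id,
               pham_id = gt$pham, stringsAsFactors = FALSE),
    external_members = setNames(as.integer(em), names(em))
  )
}

#' Write a synthetic pangenome to disk
#'
#' Emits one GenBank file per genome, a multi-FASTA of all genomes, truth
#' tables (`genome_truth.tsv`, `gene_truth.tsv`) and, when present, the
#' external reference proteins as a `[genus=...]`-tagged FASTA. Output is
#' deterministic: re-emitting the same simulation yields byte-identical
#' files.
#'
#' @param sim A `synthetic_pangenome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
emit <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_pangenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in sim$genomes) {
    f <- file.path(dir, paste0(g$id, ".gbk"))
    write_genbank(g, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "genomes.fasta")
  write_fasta(sim$genomes, f); files <- c(files, f)
  f <- file.path(dir, "genome_truth.tsv")
  write.table(sim$truth$genome_truth, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "gene_truth.tsv")
  write.table(sim$truth$gene_truth, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  if (nrow(sim$external)) {
    f <- file.path(dir, "external_proteins.faa")
    con <- file(f, "wt")
    writeLines(paste0(">", sim$external$protein_id,
                      " [genus=", sim$external$genus, "]\n",
                      sim$external$translation), con)
    close(con)
    files <- c(files, f)
  }
  invisible(files)
}
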