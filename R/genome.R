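#' Construct a genome record
#'
#' A `genome` bundles one phage (or host) nucleotide sequence with its gene
#' annotations and metadata. Gene coordinates are internal 0-based half-open
#' intervals `[start, end)` on the forward strand; GenBank I/O converts
#' to and from 1-based inclusive coordinates at the file boundary.
#'
#' @param id Unique identifier (used as FASTA header / LOCUS name).
#' @param sequence Nucleotide sequence; uppercased on construction. IUPAC
#'   ambiguity codes and `N` are permitted.
#' @param genes A data.frame with columns `gene_id`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `translation`, `function_label`, and optionally
#'   `compound` (logical flag for collapsed `join(...)` locations). May be
#'   `NULL` for an unannotated genome.
#' @param name Display name; defaults to `id`.
#' @param accession Sequence database accession, or `""`.
#' @param source_format `"genbank"`, `"fasta"` or `"constructed"`.
#' @return An object of class `genome`.
#' @examples
#' g <- genome("g1", "ACGTACGT")
#' genome_length(g)
#' @export
genome <- function(id, sequence, genes = NULL, name = id, accession = "",
                   source_format = "constructed") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("genome '", id, "': sequence is empty")
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", sequence)
  if (nzchar(bad)) {
    stop("genome '", id, "': non-nucleotide characters in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  genes <- .normalize_genes(genes, nchar(sequence), id)
  structure(
    list(id = id, name = name, accession = accession, sequence = sequence,
         genes = genes, source_format = source_format),
    class = "genome"
  )
}

.empty_genes <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), translation = character(),
             function_label = character(), compound = logical(),
             stringsAsFactors = FALSE)
}

.normalize_genes <- function(genes, genome_len, id) {
  if (is.null(genes) || nrow(genes) == 0L) return(.empty_genes())
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(genes$translation)) genes$translation <- ""
  if (is.null(genes$function_label)) genes$function_label <- ""
  if (is.null(genes$compound)) genes$compound <- FALSE
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  if (any(genes$start < 0L) || any(genes$end > genome_len) ||
      any(genes$start >= genes$end)) {
    stop("genome '", id, "': gene interval outside [0, ", genome_len,
         ") or empty")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("genome '", id, "': strand must be '+' or '-'")
  }
  tr <- toupper(genes$translation)
  tr_bad <- nzchar(gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", tr))
  if (any(tr_bad)) {
    stop("genome '", id, "': translation contains non-amino-acid letters in gene(s) ",
         paste(genes$gene_id[tr_bad], collapse = ", "))
  }
  genes$translation <- tr
  if (anyDuplicated(genes$gene_id)) {
    stop("genome '", id, "': duplicated gene_id")
  }
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  genes[, c("gene_id", "start", "end", "strand", "translation",
            "function_label", "compound")]
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s  (%s)\n", x$id,
              if (nzchar(x$accession)) x$accession else "no accession"))
  cat(sprintf("  length %s bp, %%GC %.1f, %d genes [%s]\n",
              format(genome_length(x), big.mark = ","),
              tryCatch(gc_content(x), error = function(e) NA_real_),
              nrow(x$genes), x$source_format))
  invisible(x)
}

#' Genome length in base pairs
#' @param x A `genome`.
#' @return Integer length.
#' @export
genome_length <- function(x) nchar(x$sequence)

#' G+C content of a genome
#'
#' Percent G+C over unambiguous bases: `100 * (G + C) / (A + C + G + T)`.
#' `N` and IUPAC ambiguity codes are excluded from both numerator and
#' denominator. Reported values are conventionally rounded to one decimal
#' (see [genome_metrics_table()]); this function returns full precision.
#'
#' @param x A `genome` or a nucleotide string.
#' @return Percent G+C in `[0, 100]`.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(x) {
  s <- if (inherits(x, "genome")) x$sequence else toupper(as.character(x))
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
  denom <- sum(f[c("A", "C", "G", "T")])
  if (denom == 0L) {
    stop("gc_content undefined: sequence contains no unambiguous A/C/G/T")
  }
  100 * sum(f[c("G", "C")]) / denom
}

#' Reverse complement of a nucleotide string
#' @param s Nucleotide string (IUPAC codes allowed).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Per-genome metrics table
#'
#' One row per genome with identifier, accession, exact sequence length,
#' %GC rounded to one decimal, and CDS gene count, mirroring the standard
#' "genometrics" summary of phage papers.
#'
#' @param genomes A list of `genome` objects.
#' @return A data.frame with columns `id`, `name`, `accession`, `length_bp`,
#'   `pct_gc`, `n_genes`.
#' @export
genome_metrics_table <- function(genomes) {
  genomes <- .as_genome_list(genomes)
  if (length(genomes) < 1L) stop("need at least one genome")
  data.frame(
    id = vapply(genomes, `[[`, "", "id"),
    name = vapply(genomes, `[[`, "", "name"),
    accession = vapply(genomes, `[[`, "", "accession"),
    length_bp = vapply(genomes, genome_length, 0L),
    pct_gc = round(vapply(genomes, gc_content, 0), 1),
    n_genes = vapply(genomes, function(g) nrow(g$genes), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.as_genome_list <- function(genomes) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  if (!is.list(genomes) || !all(vapply(genomes, inherits, TRUE, "genome"))) {
    stop("expected a genome or a list of genome objects")
  }
  ids <- vapply(genomes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(genomes) <- ids
  genomes
}

#' Collect all predicted proteins from a set of genomes
#'
#' Builds the protein table used by [build_phams()]. Protein ids are
#' `"<genome id>|<gene id>"` and therefore unique across the collection.
#' Genes without a translation (e.g. FASTA-only ingest) are dropped with a
#' warning.
#'
#' @param genomes A list of `genome` objects.
#' @return A data.frame with columns `protein_id`, `phage_id`, `gene_id`,
#'   `translation`.
#' @export
collect_proteins <- function(genomes) {
  genomes <- .as_genome_list(genomes)
  rows <- lapply(genomes, function(g) {
    if (nrow(g$genes) == 0L) return(NULL)
    data.frame(protein_id = paste(g$id, g$genes$gene_id, sep = "|"),
               phage_id = g$id, gene_id = g$genes$gene_id,
               translation = g$genes$translation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(protein_id = character(), phage_id = character(),
                      gene_id = character(), translation = character(),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  empty <- !nzchar(out$translation)
  if (any(empty)) {
    warning(sum(empty), " gene(s) without translation dropped from protein set")
    out <- out[!empty, , drop = FALSE]
  }
  out
}

#' Mutate a genome by i.i.d. per-site substitution
#'
#' Each position is substituted independently with probability `rate`; the
#' replacement base is drawn from `base_freq` restricted to differ from the
#' original base, so the realized divergence matches the nominal rate.
#' Gene annotations are carried over with translations recomputed from the
#' mutated sequence (bacterial code, table 11). Used for ANI calibration and
#' by the synthetic-data generator.
#'
#' @param g A `genome`.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param base_freq Named numeric vector of A/C/G/T replacement weights.
#' @return A mutated `genome` with id `"<id>_mut"`.
#' @export
mutate_genome <- function(g, rate, base_freq = c(A = 1, C = 1, G = 1, T = 1)) {
  stopifnot(inherits(g, "genome"), rate >= 0, rate <= 1)
  s <- .mutate_seq(g$sequence, rate, base_freq)
  genes <- g$genes
  if (nrow(genes) > 0L) {
    genes$translation <- vapply(seq_len(nrow(genes)), function(i) {
      cds <- substr(s, genes$start[i] + 1L, genes$end[i])
      if (genes$strand[i] == "-") cds <- revcomp(cds)
      .translate_cds(cds)
    }, "")
  }
  genome(paste0(g$id, "_mut"), s, genes, name = paste0(g$name, "_mut"),
         source_format = "constructed")
}

.mutate_seq <- function(s, rate, base_freq = c(A = 1, C = 1, G = 1, T = 1)) {
  if (rate == 0) return(s)
  bases <- strsplit(s, "")[[1]]
  hit <- which(runif(length(bases)) < rate & bases %in% c("A", "C", "G", "T"))
  if (length(hit)) {
    alphabet <- c("A", "C", "G", "T")
    for (i in hit) {
      alt <- setdiff(alphabet, bases[i])
      w <- base_freq[alt]
      bases[i] <- sample(alt, 1L, prob = w / sum(w))
    }
  }
  paste(bases, collapse = "")
}

# Translate a CDS nucleotide string with the bacterial code (table 11),
# trimming a trailing stop and any incomplete final codon. Internal stops
# are mapped to X so the result stays within the amino-acid alphabet.
.translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  cds <- substr(cds, 1L, 3L * n)
  aa <- if (grepl("[^ACGT]", cds)) {
    # ambiguity codes force the (much slower) fuzzy-codon path
    as.character(Biostrings::translate(
      Biostrings::DNAString(cds),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "X"
    ))
  } else {
    as.character(Biostrings::translate(
      Biostrings::DNAString(cds),
      genetic.code = Biostrings::getGeneticCode("11")
    ))
  }
  aa <- sub("\\*$", "", aa)
  gsub("\\*", "X", aa)
}

# vectorized variant for unambiguous CDS batches
.translate_cds_batch <- function(cds_vec) {
  n3 <- nchar(cds_vec) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(substr(cds_vec, 1L, 3L * n3)),
    genetic.code = Biostrings::getGeneticCode("11")
  ))
  aa <- sub("\\*$", "", aa)
  gsub("\\*", "X", aa)
}
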