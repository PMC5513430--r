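# GenBank flat-file ingest and export.
#
# Hand-written on purpose: the pipeline needs the feature table (CDS
# locations, strands, /translation qualifiers), and only a small, stable
# subset of the format is required. Coordinates are converted between
# GenBank's 1-based inclusive intervals and the package's 0-based half-open
# convention at this boundary.

#' Read a GenBank flat file into a genome record
#'
#' Parses the first record of a GenBank flat file. Every `CDS` feature
#' becomes one gene; `complement(...)` locations are recorded on the `-`
#' strand; compound `join(...)`/`order(...)` locations are collapsed to their
#' envelope (min..max) and flagged in the `compound` column. The
#' `/translation` qualifier is used verbatim when present, otherwise the
#' protein is translated from the nucleotide span with the bacterial genetic
#' code (table 11), trailing stop removed.
#'
#' @param path Path to a GenBank flat file containing LOCUS and ORIGIN blocks.
#' @return A [genome()] with `source_format = "genbank"`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("GenBank parse error: empty file '", path, "'")
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("GenBank parse error: no LOCUS line in '", path, "'")
  # restrict to the first record
  end_i <- grep("^//\\s*$", lines)
  last <- if (length(end_i)) end_i[1] else length(lines)
  rec <- lines[locus_i[1]:last]

  locus_name <- strsplit(trimws(sub("^LOCUS", "", rec[1])), "\\s+")[[1]][1]
  accession <- ""
  acc_i <- grep("^ACCESSION", rec)
  if (length(acc_i)) {
    acc <- strsplit(trimws(sub("^ACCESSION", "", rec[acc_i[1]])), "\\s+")[[1]][1]
    if (!is.na(acc) && nzchar(acc) && acc != ".") accession <- acc
  }
  name <- locus_name
  def_i <- grep("^DEFINITION", rec)
  if (length(def_i)) {
    d <- trimws(sub("^DEFINITION", "", rec[def_i[1]]))
    d <- sub("\\.$", "", d)
    if (nzchar(d)) name <- d
  }

  origin_i <- grep("^ORIGIN", rec)
  if (!length(origin_i)) {
    stop("GenBank parse error: missing ORIGIN block in '", path, "'")
  }
  seq_lines <- rec[(origin_i[1] + 1L):length(rec)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank parse error: empty ORIGIN in '", path, "'")

  feat_i <- grep("^FEATURES", rec)
  genes <- .empty_genes()
  if (length(feat_i)) {
    fblock <- rec[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    genes <- .parse_feature_block(fblock, nchar(sequence), locus_name)
  }
  # fall back to code-table-11 translation where /translation was absent
  if (nrow(genes)) {
    fill <- which(!nzchar(genes$translation))
    for (i in fill) {
      cds <- substr(sequence, genes$start[i] + 1L, genes$end[i])
      if (genes$strand[i] == "-") cds <- revcomp(cds)
      genes$translation[i] <- .translate_cds(cds)
    }
  }
  genome(locus_name, sequence, genes, name = name, accession = accession,
         source_format = "genbank")
}

.parse_feature_block <- function(fblock, genome_len, id) {
  starts <- grep("^ {5}\\S", fblock)
  if (!length(starts)) return(.empty_genes())
  bounds <- c(starts, length(fblock) + 1L)
  out <- list(); cds_n <- 0L
  for (k in seq_along(starts)) {
    chunk <- fblock[bounds[k]:(bounds[k + 1L] - 1L)]
    key <- strsplit(trimws(chunk[1]), "\\s+")[[1]][1]
    if (!identical(key, "CDS")) next
    cds_n <- cds_n + 1L
    qual_start <- grep("^ +/", chunk)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(chunk)
    loc <- paste(trimws(chunk[1:loc_end]), collapse = "")
    loc <- sub("^CDS\\s*", "", loc)
    parsed <- .parse_location(loc)
    quals <- .parse_qualifiers(chunk[seq_len(length(chunk)) >= loc_end + 1L])
    if (parsed$end > genome_len) {
      stop("GenBank record '", id, "' rejected: CDS feature ", cds_n,
           " (", loc, ") extends past sequence end (", genome_len, " bp)")
    }
    gene_id <- quals[["locus_tag"]] %||% quals[["gene"]] %||%
      sprintf("CDS_%03d", cds_n)
    translation <- quals[["translation"]] %||% ""
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gene_id, start = parsed$start, end = parsed$end,
      strand = parsed$strand, translation = translation,
      function_label = quals[["product"]] %||% quals[["function"]] %||% "",
      compound = parsed$compound, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(.empty_genes())
  genes <- do.call(rbind, out)
  if (anyDuplicated(genes$gene_id)) {
    genes$gene_id <- make.unique(genes$gene_id, sep = "_")
  }
  genes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GenBank location string -> 0-based half-open envelope + strand + flag
.parse_location <- function(loc) {
  compound <- grepl("join\\(|order\\(", loc)
  strand <- if (grepl("complement\\(", loc)) "-" else "+"
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 2L) stop("GenBank parse error: unparseable location '", loc, "'")
  list(start = as.integer(min(nums)) - 1L, end = as.integer(max(nums)),
       strand = strand, compound = compound)
}

.parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- trimws(lines)
  q_i <- grep("^/", txt)
  quals <- list()
  bounds <- c(q_i, length(txt) + 1L)
  for (k in seq_along(q_i)) {
    body <- paste(txt[bounds[k]:(bounds[k + 1L] - 1L)], collapse = "")
    m <- regmatches(body, regexec("^/([A-Za-z_]+)=?(.*)$", body))[[1]]
    if (length(m) < 3L) next
    val <- gsub('^"|"$', "", m[3])
    nm <- m[2]
    if (identical(nm, "translation")) val <- gsub("\\s+", "", val)
    quals[[nm]] <- val
  }
  quals
}

#' Write a genome record as a GenBank flat file
#'
#' Emits a minimal, deterministic GenBank record (LOCUS, DEFINITION,
#' ACCESSION, FEATURES with one `CDS` per gene including `/translation`,
#' and ORIGIN). [read_genbank()] of the output reproduces the sequence,
#' coordinates, strands and translations exactly.
#'
#' @param g A [genome()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  len <- genome_length(g)
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %d bp    DNA     linear   PHG 01-JAN-2000",
            g$id, len))
  w(sprintf("DEFINITION  %s.", g$name))
  if (nzchar(g$accession)) w(sprintf("ACCESSION   %s", g$accession))
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", len))
  if (nrow(g$genes)) {
    for (i in seq_len(nrow(g$genes))) {
      gn <- g$genes[i, ]
      span <- sprintf("%d..%d", gn$start + 1L, gn$end)
      if (gn$strand == "-") span <- sprintf("complement(%s)", span)
      w(sprintf("     CDS             %s", span))
      w(sprintf('                     /locus_tag="%s"', gn$gene_id))
      if (nzchar(gn$function_label)) {
        w(sprintf('                     /product="%s"', gn$function_label))
      }
      if (nzchar(gn$translation)) {
        tr <- paste0('/translation="', gn$translation, '"')
        pieces <- substring(tr, seq(1L, nchar(tr), 58L),
                            pmin(seq(1L, nchar(tr), 58L) + 57L, nchar(tr)))
        for (p in pieces) w(paste0(strrep(" ", 21), p))
      }
    }
  }
  w("ORIGIN")
  s <- tolower(g$sequence)
  for (off in seq(1L, len, 60L)) {
    chunk <- substr(s, off, min(off + 59L, len))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    w(sprintf("%9d %s", off, paste(groups, collapse = " ")))
  }
  w("//")
  invisible(path)
}
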