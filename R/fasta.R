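# FASTA ingest/export, via Biostrings.

#' Read nucleotide FASTA into genome records
#'
#' Each record becomes an unannotated [genome()] (no genes); sequences are
#' uppercased on ingest. The FASTA id (first whitespace-delimited token of
#' the header) becomes the genome id.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A named list of `genome` objects.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA error: no records in '", path, "'")
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("FASTA error: duplicate ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- lapply(seq_along(set), function(i) {
    genome(ids[i], as.character(set[[i]]), name = headers[i],
           source_format = "fasta")
  })
  names(out) <- ids
  out
}

#' Write genomes as nucleotide FASTA
#'
#' @param genomes A `genome` or list of `genome` objects.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  genomes <- .as_genome_list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a protein FASTA as an external reference set
#'
#' Headers may carry a `[genus=...]` tag identifying the host genus of the
#' source phage; untagged records get genus `"unknown"`. The result feeds
#' [attach_external()].
#'
#' @param path Path to a protein FASTA file.
#' @return A data.frame with columns `protein_id`, `genus`, `translation`.
#' @export
read_external_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA error: no records in '", path, "'")
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("FASTA error: duplicate ids in '", path, "'")
  genus <- rep("unknown", length(set))
  m <- regmatches(headers, regexpr("\\[genus=[^]]+\\]", headers))
  has <- regexpr("\\[genus=[^]]+\\]", headers) > 0
  genus[has] <- sub("\\[genus=([^]]+)\\]", "\\1", m)
  data.frame(protein_id = ids, genus = genus,
             translation = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}
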