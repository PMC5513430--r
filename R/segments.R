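# Similarity segments between two genomes for genome-map coloring:
# seeded ungapped diagonal runs above a minimum length and identity,
# greedily selected best-score-first with overlap suppression on genome A
# only (overlaps on B are permitted, so duplications remain visible).
# Indels break a run into flanking segments; that granularity is adequate
# for map shading and keeps coordinates exact.

#' Similarity segments between two genomes
#'
#' Finds ungapped locally similar segments: exact `word`-mer matches on a
#' common diagonal (per orientation) are merged into runs when consecutive
#' seeds are at most `max_gap` apart, each run's envelope is scored by
#' direct base comparison, and runs passing the length and identity floors
#' are selected greedily by score (length x identity) with overlap
#' suppression on A.
#'
#' @param a,b `genome` objects or nucleotide strings.
#' @param min_length Minimum segment length (bp) on A.
#' @param min_identity Minimum percent identity of the segment.
#' @param word Seed word length.
#' @param max_gap Maximum seed spacing (bp) merged into one run.
#' @return A data.frame of class `similarity_segments` with 0-based
#'   half-open intervals `a_start`, `a_end`, `b_start`, `b_end`, plus
#'   `orientation`, `length` and `identity` (percent), ordered by
#'   decreasing score.
#' @export
similarity_segments <- function(a, b, min_length = 200L, min_identity = 60,
                                word = 12L, max_gap = 100L) {
  sa <- if (inherits(a, "genome")) a$sequence else toupper(as.character(a))
  sb <- if (inherits(b, "genome")) b$sequence else toupper(as.character(b))
  if (!nzchar(sa) || !nzchar(sb)) stop("similarity_segments: empty sequence")
  Lb <- nchar(sb)
  cand <- rbind(.diag_runs(sa, sb, word, max_gap, "forward"),
                .diag_runs(sa, revcomp(sb), word, max_gap, "revcomp"))
  if (!is.null(cand) && nrow(cand)) {
    # map revcomp intervals back to original b coordinates
    rc <- cand$orientation == "revcomp"
    if (any(rc)) {
      b0 <- Lb - cand$b_end[rc]
      b1 <- Lb - cand$b_start[rc]
      cand$b_start[rc] <- b0
      cand$b_end[rc] <- b1
    }
    cand <- cand[cand$length >= min_length & cand$identity >= min_identity, ,
                 drop = FALSE]
  }
  out <- .empty_segments()
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(-cand$length * cand$identity), , drop = FALSE]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      sel <- which(keep)
      overlaps <- length(sel) && any(cand$a_start[i] < cand$a_end[sel] &
                                       cand$a_end[i] > cand$a_start[sel])
      keep[i] <- !overlaps
    }
    out <- cand[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("similarity_segments", "data.frame")
  out
}

.empty_segments <- function() {
  data.frame(a_start = integer(), a_end = integer(), b_start = integer(),
             b_end = integer(), orientation = character(), length = integer(),
             identity = numeric(), stringsAsFactors = FALSE)
}

# candidate runs on one orientation, coordinates on the oriented b string
.diag_runs <- function(sa, sb, w, max_gap, orientation) {
  m <- .word_matches(sa, sb, w)
  if (!nrow(m)) return(NULL)
  diag <- m$x_pos - m$y_pos
  out <- list()
  for (d in unique(diag)) {
    xs <- sort(m$x_pos[diag == d])
    grp <- cumsum(c(1L, diff(xs) > max_gap))
    for (g in unique(grp)) {
      x <- xs[grp == g]
      a0 <- x[1]; a1 <- x[length(x)] + w
      seg_a <- substr(sa, a0 + 1L, a1)
      seg_b <- substr(sb, a0 - d + 1L, a1 - d)
      idy <- 100 * mean(strsplit(seg_a, "")[[1]] == strsplit(seg_b, "")[[1]])
      out[[length(out) + 1L]] <- data.frame(
        a_start = a0, a_end = a1, b_start = a0 - d, b_end = a1 - d,
        orientation = orientation, length = a1 - a0, identity = idy,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write similarity segments as a BED-like TSV
#' @param segments Output of [similarity_segments()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_segments_tsv <- function(segments, path) {
  write.table(as.data.frame(segments), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
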