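# Exact-word dotplot between two genomes (Gepard-style content, minus the
# rendering): every shared w-mer is reported as a coordinate pair, in both
# forward and reverse-complement orientation.

#' Exact-word dotplot matrix
#'
#' Reports every position pair `(x, y)` (0-based) where the `w`-mer of `a`
#' starting at `x` equals the `w`-mer of `b` starting at `y` (orientation
#' `"forward"`), or equals the reverse complement of that `w`-mer
#' (orientation `"revcomp"`). Self-comparison contains the full main
#' diagonal.
#'
#' @param a,b `genome` objects or nucleotide strings.
#' @param w Word length (>= 4).
#' @return An object of class `dotplot_matrix`: list with `x`, `y` (ids),
#'   `w`, `len_x`, `len_y` and `matches` (data.frame `x_pos`, `y_pos`,
#'   `orientation`).
#' @export
dotplot <- function(a, b, w = 10L) {
  w <- as.integer(w)
  if (w < 4L) stop("dotplot: word length must be >= 4")
  sa <- if (inherits(a, "genome")) a$sequence else toupper(as.character(a))
  sb <- if (inherits(b, "genome")) b$sequence else toupper(as.character(b))
  ida <- if (inherits(a, "genome")) a$id else "x"
  idb <- if (inherits(b, "genome")) b$id else "y"
  empty <- data.frame(x_pos = integer(), y_pos = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  if (w > nchar(sa) || w > nchar(sb)) {
    warning("dotplot: word length exceeds a sequence; empty matrix")
    matches <- empty
  } else {
    fw <- .word_matches(sa, sb, w)
    rc <- .word_matches(sa, revcomp(sb), w)
    if (nrow(rc)) rc$y_pos <- nchar(sb) - w - rc$y_pos  # back to b coords
    matches <- rbind(
      if (nrow(fw)) cbind(fw, orientation = "forward", stringsAsFactors = FALSE) else NULL,
      if (nrow(rc)) cbind(rc, orientation = "revcomp", stringsAsFactors = FALSE) else NULL
    )
    if (is.null(matches)) matches <- empty
    matches <- matches[order(matches$x_pos, matches$y_pos), , drop = FALSE]
    rownames(matches) <- NULL
  }
  structure(list(x = ida, y = idb, w = w, len_x = nchar(sa),
                 len_y = nchar(sb), matches = matches),
            class = "dotplot_matrix")
}

# all (x0, y0) 0-based positions with identical w-mers; words containing
# ambiguity codes are not matchable
.word_matches <- function(sa, sb, w) {
  if (w > 26L) stop("word lengths above 26 are not supported")
  hits <- .code_hits(.kmer_index(sb, w), .kmer_codes(sa, w))
  data.frame(x_pos = hits$q - 1L, y_pos = hits$s - 1L,
             stringsAsFactors = FALSE)
}

#' @export
print.dotplot_matrix <- function(x, ...) {
  cat(sprintf("<dotplot_matrix> %s (%d bp) vs %s (%d bp), w = %d: %d matches\n",
              x$x, x$len_x, x$y, x$len_y, x$w, nrow(x$matches)))
  invisible(x)
}

#' @export
plot.dotplot_matrix <- function(x, cex = 0.2, ...) {
  m <- x$matches
  plot(NA, xlim = c(0, x$len_x), ylim = c(0, x$len_y),
       xlab = x$x, ylab = x$y,
       main = sprintf("dotplot, w = %d", x$w), ...)
  if (nrow(m)) {
    fw <- m$orientation == "forward"
    points(m$x_pos[fw], m$y_pos[fw], pch = ".", cex = cex, col = "black")
    points(m$x_pos[!fw], m$y_pos[!fw], pch = ".", cex = cex, col = "red3")
  }
  invisible(x)
}

#' Write dotplot matches as TSV
#' @param x A `dotplot_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dotplot_tsv <- function(x, path) {
  write.table(x$matches, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
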