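# Fragment-based average nucleotide identity (ANI), JSpecies-lineage
# scheme: the query is cut into fixed-size fragments, each fragment is
# locally aligned to its best-matching region of the subject (both strands),
# and fragments are retained if the alignment covers >= 70% of the fragment
# at >= 30% identity. ANI is the mean identity of retained fragments, with
# the retained fraction reported alongside. Candidate regions are located by
# exact k-mer seeding before alignment; a fragment with no seed support
# cannot produce an alignment passing the coverage rule and is unretained.
# A seeded fragment matching its target cleanly (>= 90% ungapped identity
# at the seeded offset) is scored by direct comparison, fastANI-style;
# only fragments below that bar go through gapped local alignment.

#' Parameters for fragment ANI
#'
#' @param fragment_size Fragment length in bp (last fragment kept when at
#'   least half this size; a genome shorter than one fragment is compared
#'   whole).
#' @param min_identity Minimum percent identity for fragment retention.
#' @param min_coverage Minimum aligned fraction of the fragment for
#'   retention.
#' @param seed_k Exact word length used to locate the candidate window.
#' @param seed_stride Sample every `seed_stride`-th fragment position for
#'   seeding.
#' @param pad Window padding (bp) either side of the seeded location.
#' @param match,mismatch,gap_opening,gap_extension Nucleotide alignment
#'   scores (penalties positive, Biostrings convention). The default gap
#'   costs are deliberately expensive so that a fragment's best local hit
#'   never crosses a structural indel: a fragment overlapping a
#'   gene-content difference then aligns only its homologous part and the
#'   coverage rule decides retention, instead of a gap-riddled alignment
#'   passing at diluted identity.
#' @return A list of class `ani_params`.
#' @export
ani_params <- function(fragment_size = 1020L, min_identity = 30,
                       min_coverage = 0.7, seed_k = 13L, seed_stride = 6L,
                       pad = 150L, match = 1, mismatch = -1,
                       gap_opening = 5, gap_extension = 2) {
  structure(list(fragment_size = as.integer(fragment_size),
                 min_identity = min_identity, min_coverage = min_coverage,
                 seed_k = as.integer(seed_k), seed_stride = as.integer(seed_stride),
                 pad = as.integer(pad), match = match, mismatch = mismatch,
                 gap_opening = gap_opening, gap_extension = gap_extension),
            class = "ani_params")
}

# k-mers are handled as base-4 integer codes (exact in doubles up to
# k = 26); windows containing ambiguity codes get NA and never match
.BASE4 <- local({
  v <- rep(NA_real_, 256)
  v[utf8ToInt("A")] <- 0; v[utf8ToInt("C")] <- 1
  v[utf8ToInt("G")] <- 2; v[utf8ToInt("T")] <- 3
  v
})

.kmer_codes <- function(s, k) {
  b <- .BASE4[utf8ToInt(s)]
  if (length(b) < k) return(numeric(0))
  as.numeric(embed(b, k) %*% 4^(0:(k - 1)))
}

# sorted-code index over every k-mer position of s
.kmer_index <- function(s, k) {
  codes <- .kmer_codes(s, k)
  ok <- which(!is.na(codes))
  o <- ok[order(codes[ok])]
  list(sorted = codes[o], pos = o, k = k)
}

# all subject positions matching each query code; returns rep'd query
# index and subject positions (vectorized run expansion)
.code_hits <- function(index, qcodes) {
  if (!length(index$sorted) || !length(qcodes)) {
    return(list(q = integer(0), s = integer(0)))
  }
  qc <- ifelse(is.na(qcodes), -1, qcodes)
  lo <- findInterval(qc - 0.5, index$sorted)
  hi <- findInterval(qc, index$sorted)
  nh <- hi - lo
  sel <- which(nh > 0L)
  if (!length(sel)) return(list(q = integer(0), s = integer(0)))
  list(q = rep.int(sel, nh[sel]),
       s = index$pos[sequence(nh[sel], from = lo[sel] + 1L)])
}

.fragment_starts <- function(L, fsize) {
  if (L <= fsize) return(data.frame(start = 1L, len = L))
  starts <- seq(1L, L, by = fsize)
  lens <- pmin(fsize, L - starts + 1L)
  keep <- lens >= fsize / 2
  data.frame(start = starts[keep], len = lens[keep])
}

# best diagonal offset (subject pos - query pos) supported by seeds;
# returns NULL when no seeds hit
.seed_offset <- function(qcodes, qpos, index) {
  hits <- .code_hits(index, qcodes)
  if (!length(hits$q)) return(NULL)
  diags <- hits$s - qpos[hits$q]
  bin <- round(diags / 100)
  tb <- table(bin)
  best <- as.integer(names(tb)[which.max(tb)])
  sel <- diags[abs(bin - best) <= 1L]
  tb2 <- table(sel)
  dominant <- max(tb2) / length(sel)
  list(offset = as.integer(names(tb2)[which.max(tb2)]), support = length(sel),
       # seeds off the dominant diagonal signal indels (or repeats)
       clean_diagonal = dominant >= 0.8)
}

# best ungapped local run (Smith-Waterman with gaps forbidden, match +1 /
# mismatch -1) over a logical match vector; returns span and identity
.best_ungapped_run <- function(m) {
  x <- ifelse(m, 1, -1)
  cs <- cumsum(x)
  prev_min <- cummin(c(0, cs[-length(cs)]))
  scores <- cs - prev_min
  end <- which.max(scores)
  start <- which(c(0, cs)[seq_len(end)] == prev_min[end])[1]
  span <- end - start + 1L
  list(span = span, identity = 100 * mean(m[start:end]))
}

.nuc_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = FALSE)
}

# one direction: fragments of q against subject s (fw/rc indexes supplied);
# fragments are aligned in one batched elementwise call against their
# seed-located candidate windows
.ani_direction <- function(q, s_fw, s_rc, idx_fw, idx_rc, params) {
  frags <- .fragment_starts(nchar(q), params$fragment_size)
  n <- nrow(frags)
  Ls <- nchar(s_fw)
  frag_seqs <- substring(q, frags$start, frags$start + frags$len - 1L)
  qcodes_all <- .kmer_codes(q, params$seed_k)
  ids <- numeric(0)
  windows <- character(0); keep <- integer(0)
  for (i in seq_len(n)) {
    if (frags$len[i] < params$seed_k) next
    qpos <- seq(1L, frags$len[i] - params$seed_k + 1L, by = params$seed_stride)
    qc <- qcodes_all[frags$start[i] + qpos - 1L]
    hit_fw <- .seed_offset(qc, qpos, idx_fw)
    hit_rc <- .seed_offset(qc, qpos, idx_rc)
    sup <- c(if (is.null(hit_fw)) 0L else hit_fw$support,
             if (is.null(hit_rc)) 0L else hit_rc$support)
    if (all(sup == 0L)) next
    use_rc <- sup[2] > sup[1]
    hit <- if (use_rc) hit_rc else hit_fw
    s <- if (use_rc) s_rc else s_fw
    # ungapped path at the seeded offset: a clean match, or a best local
    # run that settles retention, needs no gapped alignment; at the subject
    # edge only the overlapping range can align, which the coverage rule
    # already accounts for
    if (hit$clean_diagonal) {
      qs <- max(1L, 1L - hit$offset)
      qe <- min(frags$len[i], Ls - hit$offset)
      if (qe - qs + 1L < params$min_coverage * frags$len[i]) next
      sub_seq <- substr(s, hit$offset + qs, hit$offset + qe)
      m <- strsplit(substr(frag_seqs[i], qs, qe), "")[[1]] ==
        strsplit(sub_seq, "")[[1]]
      ham <- mean(m)
      if (ham >= 0.90) {
        ids <- c(ids, ham)
      } else {
        run <- .best_ungapped_run(m)
        if (run$span >= params$min_coverage * frags$len[i] &&
            run$identity >= params$min_identity) {
          ids <- c(ids, run$identity / 100)
        }
      }
      next
    }
    # seeds on several diagonals (indels): gapped local alignment against
    # the padded window
    wstart <- max(1L, hit$offset + 1L - params$pad)
    wend <- min(Ls, hit$offset + frags$len[i] + params$pad)
    if (wend <= wstart) next
    windows <- c(windows, substr(s, wstart, wend))
    keep <- c(keep, i)
  }
  if (length(keep)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(frag_seqs[keep]),
      Biostrings::DNAStringSet(windows),
      type = "local", substitutionMatrix = .nuc_matrix(params),
      gapOpening = params$gap_opening, gapExtension = params$gap_extension
    )
    span <- BiocGenerics::end(Biostrings::pattern(aln)) -
      BiocGenerics::start(Biostrings::pattern(aln)) + 1L
    identity <- Biostrings::pid(aln, type = "PID1")
    retained <- span >= params$min_coverage * frags$len[keep] &
      identity >= params$min_identity
    ids <- c(ids, identity[retained] / 100)
  }
  list(ani = if (length(ids)) mean(ids) else 0,
       aligned_fraction = length(ids) / n, n_fragments = n)
}

#' Fragment-based ANI between two genomes
#'
#' Computes ANI in both directions and the symmetrized value (the mean of
#' the two directions), on the 0-1 scale. Self-comparison gives ANI exactly
#' 1 with aligned fraction 1.
#'
#' @param a,b `genome` objects (or nucleotide strings).
#' @param params An [ani_params()] object.
#' @return An object of class `ani_result`: list with `a`, `b` (ids), `ani`,
#'   `aligned_fraction` (symmetrized), and `forward`/`reverse` per-direction
#'   results.
#' @export
fragment_ani <- function(a, b, params = ani_params()) {
  sa <- if (inherits(a, "genome")) a$sequence else toupper(as.character(a))
  sb <- if (inherits(b, "genome")) b$sequence else toupper(as.character(b))
  ida <- if (inherits(a, "genome")) a$id else "a"
  idb <- if (inherits(b, "genome")) b$id else "b"
  if (!nzchar(sa) || !nzchar(sb)) stop("fragment_ani: empty sequence")
  ab <- .ani_direction(sa, sb, revcomp(sb),
                       .kmer_index(sb, params$seed_k),
                       .kmer_index(revcomp(sb), params$seed_k), params)
  ba <- .ani_direction(sb, sa, revcomp(sa),
                       .kmer_index(sa, params$seed_k),
                       .kmer_index(revcomp(sa), params$seed_k), params)
  structure(list(a = ida, b = idb,
                 ani = mean(c(ab$ani, ba$ani)),
                 aligned_fraction = mean(c(ab$aligned_fraction,
                                           ba$aligned_fraction)),
                 forward = ab, reverse = ba, params = params),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %s vs %s: ANI %.4f, aligned fraction %.3f\n",
              x$a, x$b, x$ani, x$aligned_fraction))
  invisible(x)
}

#' All-pairs symmetrized ANI matrix
#'
#' @param genomes A list of `genome` objects.
#' @param params An [ani_params()] object.
#' @param verbose Print per-pair progress to stderr.
#' @return A list of class `ani_matrix` with square symmetric matrices
#'   `ani` and `aligned_fraction` (unit diagonals) over the genome ids.
#' @export
ani_matrix <- function(genomes, params = ani_params(), verbose = FALSE) {
  genomes <- .as_genome_list(genomes)
  ids <- names(genomes)
  n <- length(ids)
  A <- matrix(1, n, n, dimnames = list(ids, ids))
  AF <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    # per-genome k-mer indexes are reused across all pairs
    idx_fw <- lapply(genomes, function(g) .kmer_index(g$sequence, params$seed_k))
    seq_rc <- lapply(genomes, function(g) revcomp(g$sequence))
    idx_rc <- lapply(seq_rc, .kmer_index, k = params$seed_k)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (verbose) message("ANI: ", ids[i], " vs ", ids[j])
        ab <- .ani_direction(genomes[[i]]$sequence, genomes[[j]]$sequence,
                             seq_rc[[j]], idx_fw[[j]], idx_rc[[j]], params)
        ba <- .ani_direction(genomes[[j]]$sequence, genomes[[i]]$sequence,
                             seq_rc[[i]], idx_fw[[i]], idx_rc[[i]], params)
        A[i, j] <- A[j, i] <- mean(c(ab$ani, ba$ani))
        AF[i, j] <- AF[j, i] <- mean(c(ab$aligned_fraction, ba$aligned_fraction))
      }
    }
  }
  structure(list(ani = A, aligned_fraction = AF, params = params),
            class = "ani_matrix")
}

#' @export
print.ani_matrix <- function(x, ...) {
  cat(sprintf("<ani_matrix> %d genomes; ANI range %.3f-%.3f (off-diagonal)\n",
              nrow(x$ani),
              if (nrow(x$ani) > 1) min(x$ani[upper.tri(x$ani)]) else NA,
              if (nrow(x$ani) > 1) max(x$ani[upper.tri(x$ani)]) else NA))
  invisible(x)
}

#' Write an ANI matrix as a square TSV
#'
#' @param x An `ani_matrix`.
#' @param path Output path.
#' @param what `"ani"` or `"aligned_fraction"`.
#' @return Invisibly, `path`.
#' @export
write_ani_tsv <- function(x, path, what = c("ani", "aligned_fraction")) {
  what <- match.arg(what)
  m <- x[[what]]
  df <- data.frame(genome = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
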