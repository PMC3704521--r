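# Allele-specific primer-site discovery.
#
# A candidate window must be identical, gap-free and unambiguous across all
# target sequences (the primer is built on the target consensus), and its
# 3'-terminal base must mismatch every off-target sequence, with a
# configurable minimum number of mismatching columns among the three
# 3'-terminal positions (terminal mismatches are what suppress off-target
# extension).  Windows overlapping columns where an off-target is gapped
# are flagged as anchored on an insertion site, the trick of placing a
# primer across an indel private to the off-target copy.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", D = "H", H = "D", V = "B", N = "N",
                "-" = "-", "?" = "?")

revcomp <- function(chars) {
  out <- COMPLEMENT[rev(chars)]
  out[is.na(out)] <- "N"
  unname(out)
}

# Is `off` a mismatch against target base `tgt`?  Gaps mismatch; an
# ambiguity code whose base set contains the target base is conservatively
# treated as a match (it may amplify).
primer_mismatch <- function(off, tgt) {
  if (off == tgt) return(FALSE)
  if (off %in% c("-", "?")) return(TRUE)
  set <- IUPAC_SETS[[off]]
  if (is.null(set)) return(TRUE)
  !(tgt %in% set)
}

#' Find allele-specific primer candidates
#'
#' Exhaustively scans all alignment windows in the configured length range,
#' in both orientations.  A window is returned when (i) all target rows are
#' identical, gap-free and unambiguous across it, and (ii) for every
#' off-target row the 3'-terminal base mismatches and at least the
#' configured number of the three 3'-terminal columns mismatch (forward:
#' rightmost columns; reverse: leftmost columns, the primer sequence being
#' reverse-complemented).
#'
#' @param aln A `dna_alignment`.
#' @param target,offtarget Disjoint, non-empty sets of row labels.
#' @param min_len,max_len Window length bounds (alignment columns).
#' @param min_mismatch Named numeric vector, minimum per-off-target
#'   mismatch count among the three 3'-terminal columns, per orientation
#'   (default `c(forward = 1, reverse = 2)`).
#' @return Data frame of class `primer_candidates`: `orientation`, `start`,
#'   `end` (1-based inclusive), `sequence` (5'->3'),
#'   `n_three_prime_mismatches` (the minimum across off-targets) and
#'   `anchored_on_insertion`.
#' @export
find_specific_primers <- function(aln, target, offtarget,
                                  min_len = 18L, max_len = 25L,
                                  min_mismatch = c(forward = 1L,
                                                   reverse = 2L)) {
  if (length(intersect(target, offtarget)))
    stop("target and offtarget sets overlap")
  if (length(target) == 0L || length(offtarget) == 0L)
    stop("target and offtarget sets must be non-empty")
  stopifnot(all(c(target, offtarget) %in% rownames(aln)),
            min_len >= 3L, max_len >= min_len)
  mat <- unclass(aln)
  tg <- mat[target, , drop = FALSE]
  off <- mat[offtarget, , drop = FALSE]
  nc <- ncol(mat)
  # columns where the target set is usable: one shared unambiguous base
  tgt_ok <- logical(nc)
  consensus <- character(nc)
  for (k in seq_len(nc)) {
    u <- unique(tg[, k])
    if (length(u) == 1L && u %in% DNA_BASES) {
      tgt_ok[k] <- TRUE; consensus[k] <- u
    }
  }
  off_gap <- apply(off == "-", 2, any)
  rows <- list()
  for (len in seq.int(min_len, min(max_len, nc))) {
    for (start in seq_len(nc - len + 1L)) {
      end <- start + len - 1L
      win <- start:end
      if (!all(tgt_ok[win])) next
      for (orient in c("forward", "reverse")) {
        term <- if (orient == "forward") c(end, end - 1L, end - 2L)
                else c(start, start + 1L, start + 2L)
        # term[1] is the 3'-terminal column
        counts <- integer(nrow(off))
        ok <- TRUE
        for (r in seq_len(nrow(off))) {
          mm <- vapply(term, function(kk)
            primer_mismatch(off[r, kk], consensus[kk]), logical(1))
          if (!mm[1] || sum(mm) < min_mismatch[[orient]]) { ok <- FALSE; break }
          counts[r] <- sum(mm)
        }
        if (!ok) next
        seq5to3 <- if (orient == "forward") consensus[win]
                   else revcomp(consensus[win])
        rows[[length(rows) + 1L]] <- data.frame(
          orientation = orient, start = start, end = end,
          sequence = paste(seq5to3, collapse = ""),
          n_three_prime_mismatches = min(counts),
          anchored_on_insertion = any(off_gap[win]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(orientation = character(0), start = integer(0),
                         end = integer(0), sequence = character(0),
                         n_three_prime_mismatches = integer(0),
                         anchored_on_insertion = logical(0))
  structure(out, class = c("primer_candidates", "data.frame"))
}

#' Re-check the specificity of a primer candidate
#'
#' Recomputes, per off-target sequence, the number of mismatching columns
#' among the candidate's three 3'-terminal positions, and verifies the
#' stored `n_three_prime_mismatches` (the minimum across off-targets).
#'
#' @param primer One row of a `primer_candidates` data frame (or a list
#'   with the same fields).
#' @param aln The `dna_alignment` the candidate was found in.
#' @param offtarget Off-target row labels.
#' @return List with `per_offtarget` (named integer vector of terminal
#'   mismatch counts), `gap_under_terminal` (named logical: the 3' base
#'   sits on an off-target gap) and `stored_count_ok`.
#' @export
check_specificity <- function(primer, aln, offtarget) {
  stopifnot(all(offtarget %in% rownames(aln)))
  mat <- unclass(aln)
  win <- primer$start:primer$end
  if (primer$start < 1L || primer$end > ncol(mat))
    stop("primer window outside the alignment")
  term <- if (primer$orientation == "forward")
    c(primer$end, primer$end - 1L, primer$end - 2L)
  else c(primer$start, primer$start + 1L, primer$start + 2L)
  # reconstruct the alignment-orientation target consensus of the window
  seq_chars <- strsplit(primer$sequence, "", fixed = TRUE)[[1]]
  consensus_win <- if (primer$orientation == "forward") seq_chars
                   else revcomp(seq_chars)
  consensus <- stats::setNames(consensus_win, win)
  counts <- integer(length(offtarget))
  gap_term <- logical(length(offtarget))
  for (r in seq_along(offtarget)) {
    mm <- vapply(term, function(kk)
      primer_mismatch(mat[offtarget[r], kk],
                      consensus[[as.character(kk)]]), logical(1))
    counts[r] <- sum(mm)
    gap_term[r] <- mat[offtarget[r], term[1]] == "-"
  }
  names(counts) <- names(gap_term) <- offtarget
  list(per_offtarget = counts, gap_under_terminal = gap_term,
       stored_count_ok = min(counts) == primer$n_three_prime_mismatches)
}
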