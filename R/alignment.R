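# Multiple sequence alignments and Jukes-Cantor distances.
#
# Alignments are stored as upper-case character matrices (rows = sequences,
# labelled; columns = alignment positions) over the alphabet
# {A,C,G,T, IUPAC ambiguity codes, '-', '?', 'N'}.  All column coordinates
# in this package are 1-based and inclusive.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity code -> set of bases it covers
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base set -> IUPAC code (key = sorted bases pasted together)
IUPAC_CODES <- local({
  codes <- names(IUPAC_SETS)
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""),
                 character(1))
  stats::setNames(codes, keys)
})

iupac_union <- function(a, b) {
  sa <- IUPAC_SETS[[a]]; sb <- IUPAC_SETS[[b]]
  if (is.null(sa) || is.null(sb)) return("N")
  IUPAC_CODES[[paste(sort(unique(c(sa, sb))), collapse = "")]]
}

#' Construct an alignment
#'
#' @param x Named character vector of equal-length sequence strings, a named
#'   list of single-character vectors, or a character matrix with rownames.
#' @return A `dna_alignment` (character matrix, rows = sequences).
#' @export
dna_alignment <- function(x) {
  if (is.matrix(x)) {
    mat <- x
  } else if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1L)
      stop("ragged alignment; offending labels: ",
           paste(names(x)[lens != stats::median(lens)], collapse = ", "))
    mat <- do.call(rbind, x)
  } else {
    stopifnot(is.character(x))
    lens <- nchar(x)
    if (length(unique(lens)) > 1L)
      stop("ragged alignment; offending labels: ",
           paste(names(x)[lens != stats::median(lens)], collapse = ", "))
    mat <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(mat) <- names(x)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("sequence labels must be present and unique")
  mat[] <- toupper(mat)
  structure(mat, class = c("dna_alignment", "matrix", "array"))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("dna_alignment:", nrow(x), "sequences x", ncol(x), "columns\n")
  invisible(x)
}

# sequences as named strings
aln_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

as_seq_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "")[[1]]
  else toupper(as.character(x))
}

#' Read an alignment from FASTA or NEXUS
#'
#' Sequences are upper-cased on read; a ragged FASTA is rejected with the
#' offending labels named.
#'
#' @param file Path.
#' @param format `"auto"` (by content), `"fasta"` or `"nexus"`.
#' @return A [dna_alignment()].
#' @export
read_alignment <- function(file, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  if (format == "fasta") {
    recs <- ape::read.FASTA(file)
    chars <- lapply(as.character(recs), toupper)
  } else {
    chars <- lapply(ape::read.nexus.data(file), toupper)
  }
  lens <- lengths(chars)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment; offending labels: ",
         paste(names(chars)[lens != stats::median(lens)], collapse = ", "))
  dna_alignment(chars)
}

#' Write an alignment to FASTA or NEXUS
#'
#' @param aln A `dna_alignment`.
#' @param file Path.
#' @param format `"fasta"` or `"nexus"`.
#' @param width Line width for FASTA output.
#' @return `file`, invisibly.
#' @export
write_alignment <- function(aln, file, format = c("fasta", "nexus"),
                            width = 70L) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- aln_strings(aln)
    con <- file(file, "w")
    on.exit(close(con))
    for (lab in names(seqs)) {
      writeLines(paste0(">", lab), con)
      s <- seqs[[lab]]
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                 con)
    }
  } else {
    ape::write.nexus.data(
      stats::setNames(lapply(seq_len(nrow(aln)),
                             function(i) unclass(aln)[i, ]), rownames(aln)),
      file = file, format = "dna", interleaved = FALSE)
  }
  invisible(file)
}

#' Remove alignment columns touched by indels
#'
#' Retains exactly the columns containing no gap character (`-`) in any
#' sequence, preserving column order.  `?` and `N` count as missing data,
#' not as gaps.
#'
#' @param aln A `dna_alignment`.
#' @return List with `alignment` (the pruned `dna_alignment`) and
#'   `column_map` (for each retained column, its original 1-based index).
#' @export
prune_indel_columns <- function(aln) {
  stopifnot(ncol(aln) > 0L)
  has_gap <- apply(unclass(aln) == "-", 2, any)
  keep <- which(!has_gap)
  if (length(keep) == 0L)
    warning("all columns contain gaps; returning an empty alignment")
  out <- unclass(aln)[, keep, drop = FALSE]
  rownames(out) <- rownames(aln)
  list(alignment = structure(out, class = class(aln)), column_map = keep)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' Compares only columns where both sequences carry an unambiguous base
#' (pairwise deletion; gaps, `?`, `N` and IUPAC ambiguity codes are treated
#' as missing).  With mismatch proportion `p`, returns
#' `d = -(3/4) * log(1 - (4/3) p)` substitutions per site.  The distance is
#' undefined (`NA`) when `p >= 3/4` or when no valid columns remain.
#'
#' @param seq_a,seq_b Aligned sequences (strings or character vectors) of
#'   equal length.
#' @return Distance in substitutions/site, or `NA` when undefined.
#' @export
jc_distance <- function(seq_a, seq_b) {
  a <- as_seq_vector(seq_a)
  b <- as_seq_vector(seq_b)
  if (length(a) != length(b)) stop("sequences differ in length")
  valid <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(valid)
  if (n == 0L) return(NA_real_)
  p <- sum(a[valid] != b[valid]) / n
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Jukes-Cantor distance matrix
#'
#' @param aln A `dna_alignment`.
#' @return Symmetric numeric matrix (zero diagonal) with `NA` marking
#'   undefined entries.
#' @export
jc_matrix <- function(aln) {
  n <- nrow(aln)
  labs <- rownames(aln)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  mat <- unclass(aln)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- jc_distance(mat[i, ], mat[j, ])
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

#' Concordance between two distance matrices
#'
#' Compares corresponding off-diagonal entries of two distance matrices over
#' a set of shared individuals (e.g. distances among the extra gene copies
#' of several specimens against distances among the primary copies of the
#' same specimens, the contamination-control argument).
#'
#' @param mat_a,mat_b Distance matrices with labelled rows/columns.
#' @param shared Either a character vector of labels present in both
#'   matrices, or a two-column data frame mapping labels in `mat_a` to the
#'   corresponding labels in `mat_b`.  At least three individuals.
#' @return List with `max_abs_diff`, `pearson_r`, `n_pairs` (pairs
#'   compared) and `n_dropped` (pairs lost to undefined distances).
#' @export
distance_concordance <- function(mat_a, mat_b, shared) {
  if (is.data.frame(shared)) {
    la <- as.character(shared[[1]]); lb <- as.character(shared[[2]])
  } else {
    la <- lb <- as.character(shared)
  }
  if (length(la) < 3L)
    stop("need at least three shared individuals")
  stopifnot(all(la %in% rownames(mat_a)), all(lb %in% rownames(mat_b)))
  da <- db <- numeric(0)
  n_dropped <- 0L
  for (i in seq_len(length(la) - 1L)) {
    for (j in (i + 1L):length(la)) {
      va <- mat_a[la[i], la[j]]
      vb <- mat_b[lb[i], lb[j]]
      if (is.na(va) || is.na(vb)) { n_dropped <- n_dropped + 1L; next }
      da <- c(da, va); db <- c(db, vb)
    }
  }
  if (length(da) == 0L)
    stop("no defined distance pairs to compare")
  r <- if (stats::sd(da) == 0 || stats::sd(db) == 0) NA_real_
       else stats::cor(da, db)
  list(max_abs_diff = max(abs(da - db)), pearson_r = r,
       n_pairs = length(da), n_dropped = n_dropped)
}

#' Alignment summary statistics
#'
#' Gaps, `?`, `N` and IUPAC ambiguity codes are treated as missing.  A
#' column is constant when exactly one distinct unambiguous state occurs
#' among its non-missing cells, and parsimony-informative when at least two
#' states each occur in at least two sequences.
#'
#' @param aln A `dna_alignment`.
#' @return List with `n_taxa`, `n_columns`, `n_parsimony_informative`,
#'   `n_constant`.
#' @export
alignment_stats <- function(aln) {
  stopifnot(nrow(aln) > 0L, ncol(aln) > 0L)
  mat <- unclass(aln)
  n_const <- 0L
  n_pi <- 0L
  for (k in seq_len(ncol(mat))) {
    col <- mat[, k]
    col <- col[col %in% DNA_BASES]
    if (length(col) == 0L) next
    tab <- table(col)
    if (length(tab) == 1L) n_const <- n_const + 1L
    else if (sum(tab >= 2L) >= 2L) n_pi <- n_pi + 1L
  }
  list(n_taxa = nrow(mat), n_columns = ncol(mat),
       n_parsimony_informative = n_pi, n_constant = n_const)
}

#' Write a distance matrix as a lower-triangle table
#'
#' Tab-separated lower triangle with a header row; entries printed with five
#' decimals, `NA` for undefined distances.
#'
#' @param m Distance matrix.
#' @param file Path, or `NULL` to return the lines.
#' @return Character vector of lines, invisibly when written.
#' @export
write_distance_table <- function(m, file = NULL) {
  labs <- rownames(m)
  lines <- paste(c("", labs), collapse = "\t")
  for (i in seq_along(labs)) {
    vals <- if (i == 1L) character(0)
            else sprintf("%.5f", m[i, seq_len(i - 1L)])
    vals[is.na(m[i, seq_len(i - 1L)])[seq_along(vals)]] <- "NA"
    lines <- c(lines, paste(c(labs[i], vals), collapse = "\t"))
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Published Jukes-Cantor distances among Silene NRPA2 gene copies
#'
#' Pairwise Jukes-Cantor distances among the NRPA2 a- and b-copies carried
#' by the five Silene (section Physolychnis) specimens in which both copies
#' co-occur, as printed in the source study (computed there in PAUP*).  Used
#' by the contamination-control concordance check: if the b-copies were
#' cross-sample contaminants, distances among them would not mirror the
#' distances among the a-copies of the same individuals.
#'
#' @return List of three 5x5 matrices: `a` (distances among a-copies), `b`
#'   (among b-copies) and `between` (a-copy vs b-copy, rows = a), all with
#'   specimen labels.
#' @export
nrpa2_copy_distances <- function() {
  specimens <- c("S_villosula_12211", "S_linnaeana_12405",
                 "S_sachalinensis_6678", "S_samojedora_12338",
                 "S_viscosa_7705")
  lt <- function(vals) {
    m <- matrix(0, 5, 5, dimnames = list(specimens, specimens))
    k <- 1L
    for (i in 2:5) for (j in seq_len(i - 1L)) {
      m[i, j] <- m[j, i] <- vals[k]; k <- k + 1L
    }
    m
  }
  a <- lt(c(0.00665,
            0.00311, 0.00512,
            0.00608, 0.00503, 0.00321,
            0.02705, 0.02321, 0.02486, 0.02483))
  b <- lt(c(0.00287,
            0.00428, 0.00294,
            0.00434, 0.00596, 0.00579,
            0.00549, 0.00754, 0.01008, 0.00874))
  between <- matrix(c(
    0.08784, 0.07920, 0.08586, 0.08784, 0.08967,
    0.08198, 0.07990, 0.08409, 0.08617, 0.08631,
    0.08430, 0.07831, 0.08645, 0.08822, 0.08838,
    0.08259, 0.07720, 0.07912, 0.08448, 0.08445,
    0.09502, 0.09028, 0.08895, 0.09424, 0.09329),
    nrow = 5, byrow = TRUE, dimnames = list(specimens, specimens))
  list(a = a, b = b, between = between)
}
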