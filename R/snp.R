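# Diagnostic-SNP detection and query classification against two clade
# references, the logic behind scoring amplified sequences as a-copy-like,
# b-copy-like, or polymorphic (heterozygous chromatograms reading as IUPAC
# superpositions of both copies).

#' Find diagnostic sites between two reference sets
#'
#' A column is diagnostic when all reference-a rows share one unambiguous
#' base, all reference-b rows share one unambiguous base, and the two bases
#' differ.  Indel-touched columns should be removed first
#' ([prune_indel_columns()]).
#'
#' @param aln A `dna_alignment`.
#' @param ref_a,ref_b Non-empty character vectors of row labels serving as
#'   the two clade references.
#' @return Object of class `diagnostic_sites`: data frame with `column`
#'   (1-based), `state_a`, `state_b`; columns strictly increasing.
#' @export
find_diagnostic_sites <- function(aln, ref_a, ref_b) {
  if (length(ref_a) == 0L || length(ref_b) == 0L)
    stop("reference sets must be non-empty")
  stopifnot(all(ref_a %in% rownames(aln)), all(ref_b %in% rownames(aln)))
  ma <- unclass(aln)[ref_a, , drop = FALSE]
  mb <- unclass(aln)[ref_b, , drop = FALSE]
  fixed_state <- function(col) {
    u <- unique(col)
    if (length(u) == 1L && u %in% DNA_BASES) u else NA_character_
  }
  sa <- apply(ma, 2, fixed_state)
  sb <- apply(mb, 2, fixed_state)
  hit <- which(!is.na(sa) & !is.na(sb) & sa != sb)
  structure(data.frame(column = hit, state_a = sa[hit], state_b = sb[hit],
                       row.names = NULL),
            class = c("diagnostic_sites", "data.frame"))
}

# per-site call for one query character against one diagnostic site
site_call <- function(q, state_a, state_b) {
  if (q %in% c("-", "?", "N")) return("missing")
  if (q == state_a) return("a")
  if (q == state_b) return("b")
  set <- IUPAC_SETS[[q]]
  if (is.null(set)) return("other")
  if (all(c(state_a, state_b) %in% set)) return("both")
  "other"
}

#' Classify a query sequence against a diagnostic site set
#'
#' Per-site calls: the query base matches the a-state (`a`), the b-state
#' (`b`), is an IUPAC code covering both states (`both`, the signature of a
#' heterozygous chromatogram), is missing (`-`, `?`, `N`), or is some other
#' state (`other`).  The class is `A` or `B` when all informative calls
#' point one way, `BOTH` when a both-call is present and the remaining
#' calls are consistent, `MOSAIC` when substantial a- and b-calls co-occur
#' without ambiguity, and `NEITHER` without informative calls.  A single
#' contradictory site does not flip the class; it is counted in
#' `n_other_clade_diagnostic` (treated as an isolated case of homoplasy).
#'
#' @param query Aligned sequence (string or character vector) on the same
#'   coordinates as the alignment the sites came from.
#' @param sites A `diagnostic_sites` object.
#' @param label Optional query label carried into the report row.
#' @return One-row data frame: `label`, `n_sites_compared`, `n_match_a`,
#'   `n_match_b`, `n_match_both`, `n_other`, `n_missing`, `class`,
#'   `n_other_clade_diagnostic`.
#' @export
classify_query <- function(query, sites, label = "query") {
  q <- as_seq_vector(query)
  if (nrow(sites) > 0L && max(sites$column) > length(q))
    stop("query shorter than the alignment the sites were found in")
  calls <- character(nrow(sites))
  for (k in seq_len(nrow(sites)))
    calls[k] <- site_call(q[sites$column[k]], sites$state_a[k],
                          sites$state_b[k])
  n_a <- sum(calls == "a"); n_b <- sum(calls == "b")
  n_both <- sum(calls == "both"); n_other <- sum(calls == "other")
  n_missing <- sum(calls == "missing")
  informative <- n_a + n_b + n_both
  minority <- min(n_a, n_b)
  if (informative == 0L) {
    cls <- "NEITHER"; n_contra <- 0L
  } else if (n_a > 0L && n_b > 0L) {
    if (minority == 1L && n_a != n_b) {
      # lone contradictory site: report, do not flip the class
      cls <- if (n_both > 0L) "BOTH" else if (n_a > n_b) "A" else "B"
      n_contra <- 1L
    } else {
      cls <- "MOSAIC"; n_contra <- minority
    }
  } else if (n_both > 0L) {
    cls <- "BOTH"; n_contra <- 0L
  } else if (n_a > 0L) {
    cls <- "A"; n_contra <- 0L
  } else {
    cls <- "B"; n_contra <- 0L
  }
  data.frame(label = label, n_sites_compared = nrow(sites),
             n_match_a = n_a, n_match_b = n_b, n_match_both = n_both,
             n_other = n_other, n_missing = n_missing, class = cls,
             n_other_clade_diagnostic = n_contra,
             stringsAsFactors = FALSE)
}

#' Classify every sequence of an alignment
#'
#' @param aln A `dna_alignment`.
#' @param sites A `diagnostic_sites` object on the same coordinates.
#' @param queries Row labels to classify (default: all rows).
#' @return Data frame of [classify_query()] rows.
#' @export
classify_alignment <- function(aln, sites, queries = rownames(aln)) {
  do.call(rbind, lapply(queries, function(lab)
    classify_query(unclass(aln)[lab, ], sites, label = lab)))
}

#' Split a polymorphic query into its two haplotypes
#'
#' For a query classified `BOTH` (an IUPAC superposition of one a-like and
#' one b-like haplotype), resolves each covering ambiguity at a diagnostic
#' site toward the a-state in one output and toward the b-state in the
#' other.  Non-diagnostic ambiguities are left intact.  Diagnostic sites
#' whose state is neither a reference state nor a covering code are carried
#' through unchanged and flagged.
#'
#' @param query Aligned sequence (string or character vector).
#' @param sites A `diagnostic_sites` object.
#' @return List with `haplotype_a`, `haplotype_b` (character vectors) and
#'   `unresolved` (1-based columns carried through unchanged).
#' @export
split_polymorphic <- function(query, sites) {
  q <- as_seq_vector(query)
  row <- classify_query(q, sites)
  if (row$class != "BOTH")
    stop("split_polymorphic() expects a query classified BOTH, got ",
         row$class)
  ha <- hb <- q
  unresolved <- integer(0)
  for (k in seq_len(nrow(sites))) {
    col <- sites$column[k]
    call <- site_call(q[col], sites$state_a[k], sites$state_b[k])
    if (call == "both") {
      ha[col] <- sites$state_a[k]
      hb[col] <- sites$state_b[k]
    } else if (call == "other") {
      unresolved <- c(unresolved, col)
    }
    # unambiguous a- or b-calls are left as observed in both haplotypes,
    # so re-superposing the outputs reproduces the query exactly
  }
  list(haplotype_a = ha, haplotype_b = hb, unresolved = unresolved)
}

#' Aggregate classification rows into a per-group summary table
#'
#' Mirrors the reporting layout of multi-primer amplification screens:
#' column `A` counts readable sequences per group, `B` counts sequences
#' matching the clade-a reference (classes `A` and `BOTH`), `C` those
#' matching the clade-b reference (classes `B` and `BOTH`).  Sequences with
#' `n_other_clade_diagnostic >= 1` are listed as footnote-style
#' annotations.
#'
#' @param reports Data frame of [classify_query()] rows.
#' @param groups Named character vector mapping sequence label to group
#'   name; unlisted sequences form their own group per label.
#' @return List with `table` (data frame: `group`, `A`, `B`, `C`) and
#'   `annotations` (data frame: `group`, `label`,
#'   `n_other_clade_diagnostic`).
#' @export
tabulate_report <- function(reports, groups = NULL) {
  grp <- if (is.null(groups)) reports$label
         else ifelse(reports$label %in% names(groups),
                     groups[reports$label], reports$label)
  levels_seen <- unique(c(grp, unname(groups)))
  rows <- lapply(levels_seen, function(g) {
    sub <- reports[grp == g, , drop = FALSE]
    data.frame(group = g, A = nrow(sub),
               B = sum(sub$class %in% c("A", "BOTH")),
               C = sum(sub$class %in% c("B", "BOTH")))
  })
  ann <- reports[reports$n_other_clade_diagnostic >= 1L,
                 c("label", "n_other_clade_diagnostic"), drop = FALSE]
  ann <- data.frame(group = if (nrow(ann)) grp[reports$n_other_clade_diagnostic >= 1L] else character(0),
                    ann, row.names = NULL)
  list(table = do.call(rbind, rows), annotations = ann)
}
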