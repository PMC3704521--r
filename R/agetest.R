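# Relative node-age hypothesis tests on 95% HPD age intervals.
#
# The discrimination logic is eliminative and interval-based: two node-age
# HPD intervals either overlap (closed-interval convention: a shared
# endpoint counts) or they do not.  Introgression is *consistent* when the
# divergence of the extra copies (node d) overlaps in age with the
# divergence of the primary copies of the recipient clade (node c).
# Paralogy (and equally incomplete lineage sorting) is *rejected* when a
# node nested under d in the duplication reading (node e) is strictly older
# than d, i.e. the two HPD intervals are disjoint with hpd(e) above hpd(d).

validate_interval <- function(i, what = "interval") {
  if (length(i) != 2L || !is.numeric(i) || any(!is.finite(i)))
    stop(what, " must be two finite numbers c(lower, upper)")
  if (any(i < 0)) stop(what, " bounds must be non-negative (ages in Ma)")
  if (i[1] > i[2]) stop(what, " has lower > upper")
  invisible(i)
}

#' Do two HPD intervals overlap?
#'
#' Closed-interval convention: a shared endpoint counts as overlap.
#'
#' @param i,j Intervals `c(lower, upper)` in Ma.
#' @return Logical.
#' @export
hpd_overlap <- function(i, j) {
  validate_interval(i); validate_interval(j)
  max(i[1], j[1]) <= min(i[2], j[2])
}

#' Elapsed divergence between a clade split and a later event
#'
#' Interval arithmetic for "how long had the lineages been separated when
#' the event happened": given the split-age interval and the event-age
#' interval, returns `[max(0, split_lo - event_hi), split_hi - event_lo]`.
#'
#' @param split,event Intervals `c(lower, upper)` in Ma.
#' @return Interval `c(lower, upper)` in Ma.
#' @export
elapsed_divergence <- function(split, event) {
  validate_interval(split, "split"); validate_interval(event, "event")
  if (split[2] < event[1])
    stop("event postdates the split everywhere; no elapsed divergence")
  c(max(0, split[1] - event[2]), split[2] - event[1])
}

# round half up (R's round() is round-half-even); eps guards binary
# representation of decimal midpoints
round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  floor(x * s + 0.5 + sqrt(.Machine$double.eps)) / s
}

#' Interval midpoint, rounded half-up
#'
#' @param i Interval `c(lower, upper)`.
#' @param digits Decimals to round to (half-up, the reporting convention
#'   for ages in Ma).
#' @return Numeric midpoint.
#' @export
interval_midpoint <- function(i, digits = 1L) {
  validate_interval(i)
  round_half_up((i[1] + i[2]) / 2, digits)
}

#' Evaluate the introgression / paralogy / lineage-sorting hypotheses
#'
#' Requires designations for nodes `c`, `d` and `e` on a dated tree whose
#' designated nodes carry 95% HPD intervals:
#' * `introgression_consistent` -- hpd(c) and hpd(d) overlap (both copies
#'   coalesce with their parental lineages at compatible times);
#' * `paralogy_rejected` and `ils_rejected` -- hpd(e) lies strictly above
#'   hpd(d) (`hpd(e) lower > hpd(d) upper`): a node that the duplication
#'   (or lineage-sorting) reading requires to be nested under the clade
#'   split is in fact older, so both readings fail.  The two rejections
#'   rest on the same interval comparison and are always equal.
#'
#' @param tree A `dated_tree` with HPD intervals.
#' @param designations Named integer vector with entries `c`, `d`, `e`
#'   (node ids), e.g. from [designate_nodes()].
#' @return Object of class `verdict`: list with the flags, the interval
#'   comparisons behind them, and a narrative trace.
#' @export
evaluate_hypotheses <- function(tree, designations) {
  need <- c("c", "d", "e")
  missing <- setdiff(need, names(designations))
  if (length(missing))
    stop("missing node designation(s): ", paste(missing, collapse = ", "))
  if (designations[["d"]] == designations[["e"]])
    stop("designations d and e must name distinct nodes")
  get_hpd <- function(letter) {
    v <- designations[[letter]]
    iv <- tree$hpd[v, ]
    if (anyNA(iv))
      stop("designated node '", letter, "' (node ", v,
           ") carries no HPD interval")
    validate_interval(iv, paste0("hpd(", letter, ")"))
  }
  hc <- get_hpd("c"); hd <- get_hpd("d"); he <- get_hpd("e")
  intro <- hpd_overlap(hc, hd)
  rejected <- he[1] > hd[2]
  narrative <- c(
    sprintf("hpd(c) = [%.4g, %.4g] Ma; hpd(d) = [%.4g, %.4g] Ma; %s.",
            hc[1], hc[2], hd[1], hd[2],
            if (intro) "the intervals overlap, consistent with a single introgression event at the age of node d"
            else "the intervals are disjoint, inconsistent with simultaneous coalescence of both copies"),
    sprintf("hpd(e) = [%.4g, %.4g] Ma vs hpd(d) = [%.4g, %.4g] Ma: %s.",
            he[1], he[2], hd[1], hd[2],
            if (rejected) "node e is strictly older, so a duplication (or lineage-sorting) history placing the clade split at node d is rejected under the HPD-disjunction rule"
            else "node e is not strictly older than node d, so the duplication and lineage-sorting readings are not rejected"))
  structure(list(introgression_consistent = intro,
                 paralogy_rejected = rejected,
                 ils_rejected = rejected,
                 comparisons = list(
                   c_vs_d = list(hpd_c = hc, hpd_d = hd, overlap = intro),
                   e_vs_d = list(hpd_e = he, hpd_d = hd,
                                 e_strictly_older = rejected)),
                 narrative = narrative),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat("verdict:\n")
  cat("  introgression consistent:", x$introgression_consistent, "\n")
  cat("  paralogy rejected:       ", x$paralogy_rejected, "\n")
  cat("  lineage sorting rejected:", x$ils_rejected, "\n")
  for (ln in x$narrative) cat("  -", ln, "\n")
  invisible(x)
}
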