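# Physician transition-responsibility count matrices (PTRCM) and the
# prescribing indexes derived from them.
#
# A physician's PTRCM is an 8x8 matrix whose (i, j) entry is the weighted
# number of patient prescription-state transitions i -> j for which the
# physician was deemed responsible (co-responsible physicians share a
# transition with weights summing to 1). Entries above the diagonal are
# prescribing transitions, entries below are deprescribing; the diagonal
# is identically zero because continuations never emit a transition.

#' Build per-physician transition-responsibility count matrices
#'
#' @param transitions Long transition table (one row per transition and
#'   responsible physician), as produced by
#'   [extract_prescribing_transitions()] / [attribute_deprescribing()] and
#'   combined with [combine_transitions()]. Rows with `NA` physician
#'   (unattributed transitions) are ignored.
#' @return Named list of 8x8 matrices, one per physician, with state
#'   labels as dimnames.
#' @export
build_ptrcm <- function(transitions) {
  tx <- as.data.table(transitions)
  tx <- tx[!is.na(physician_id)]
  if (nrow(tx) == 0L) return(structure(list(), names = character(0)))
  if (any(tx$from_state == tx$to_state)) {
    stop("self-transitions (from_state == to_state) are not allowed")
  }
  agg <- tx[, .(weight = sum(weight)),
            by = .(physician_id = as.character(physician_id),
                   from_state, to_state)]
  ids <- sort(unique(agg$physician_id))
  out <- lapply(ids, function(k) {
    m <- matrix(0, 8L, 8L, dimnames = list(STATE_LABELS, STATE_LABELS))
    sub <- agg[physician_id == k]
    m[cbind(sub$from_state, sub$to_state)] <- sub$weight
    m
  })
  names(out) <- ids
  out
}

ptrcm_check <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(8L, 8L)))
  if (any(m < 0)) stop("PTRCM entries must be nonnegative")
  if (any(diag(m) != 0)) stop("PTRCM diagonal must be zero")
  invisible(m)
}

# weight |drug_count(i) - drug_count(j)|^alpha with the 0^0 = 1 convention
dc_weight <- function(alpha) {
  dc <- STATE_DRUG_COUNT
  w <- abs(outer(dc, dc, "-"))^alpha
  if (alpha == 0) w[] <- 1
  w
}

#' Prescribing-deprescribing balance index
#'
#' Computes `(P - D) / (P + D)` where `P` sums the above-diagonal
#' (prescribing) entries of the PTRCM and `D` the below-diagonal
#' (deprescribing) entries, each weighted by the number of drug classes
#' changed raised to the power `alpha`. With `alpha = 0` every transition
#' counts equally (the base index); with `alpha = 1` transitions are
#' weighted by how many drugs they add or remove. The index lies in
#' `(-1, 1]` and is `NA` (undefined) when the physician has no weighted
#' transition mass.
#'
#' @param m An 8x8 PTRCM.
#' @param alpha 0 or 1.
#' @return A real in `(-1, 1]`, or `NA_real_` when undefined.
#' @export
index_alpha <- function(m, alpha = 0) {
  ptrcm_check(m)
  if (!alpha %in% c(0, 1)) stop("alpha must be 0 or 1")
  w <- dc_weight(alpha)
  up <- upper.tri(m)
  lo <- lower.tri(m)
  P <- sum(m[up] * w[up])
  D <- sum(m[lo] * w[lo])
  if (P + D == 0) return(NA_real_)
  (P - D) / (P + D)
}

#' Involvement in transitions into the all-three-classes state
#'
#' Fraction of a physician's total transition responsibility that brought
#' patients into state 8 (all three drug classes concurrently).
#'
#' @param m An 8x8 PTRCM.
#' @return A real in `[0, 1]`; 0 when the physician has transitions but
#'   none into state 8; `NA_real_` when the physician has no transitions.
#' @export
index_obs <- function(m) {
  ptrcm_check(m)
  total <- sum(m[upper.tri(m)]) + sum(m[lower.tri(m)])
  if (total == 0) return(NA_real_)
  sum(m[1:7, 8L]) / total
}

#' Ever brought a patient into the all-three-classes state
#'
#' @param m An 8x8 PTRCM.
#' @return 1 if the physician has any (possibly fractional) responsibility
#'   for a transition into state 8, else 0.
#' @export
ever_obs <- function(m) {
  ptrcm_check(m)
  as.integer(sum(m[1:7, 8L]) > 0)
}

#' Fraction of transitions changing two or more drug classes
#'
#' Among a physician's transitions in the given direction, the weighted
#' fraction whose drug-count change is at least 2 (e.g. state zero to OBS
#' changes three drugs; OBS to B changes two).
#'
#' @param m An 8x8 PTRCM.
#' @param direction `"prescribing"` (above-diagonal mass) or
#'   `"deprescribing"` (below-diagonal mass).
#' @return A real in `[0, 1]`. With no deprescribing mass the
#'   deprescribing index is 0 by convention; with no prescribing mass the
#'   prescribing index is `NA_real_` (undefined).
#' @export
two_or_more <- function(m, direction = c("prescribing", "deprescribing")) {
  ptrcm_check(m)
  direction <- match.arg(direction)
  w <- dc_weight(1)
  tri <- if (direction == "prescribing") upper.tri(m) else lower.tri(m)
  denom <- sum(m[tri])
  if (denom == 0) {
    return(if (direction == "deprescribing") 0 else NA_real_)
  }
  sum(m[tri] * (w[tri] >= 2)) / denom
}

#' Prescribing profiles for a set of physicians
#'
#' Evaluates the six prescribing indexes on each physician's PTRCM.
#'
#' @param ptrcms Named list of PTRCMs from [build_ptrcm()].
#' @return `data.table` with columns `physician_id`, `I0`, `I1`, `IOBS`,
#'   `IeverOBS`, `Ipresc2mr`, `Idepresc2mr` and `n_transitions` (total
#'   weighted transition mass). Undefined indexes are `NA`.
#' @export
prescribing_profiles <- function(ptrcms) {
  if (length(ptrcms) == 0L) {
    return(data.table(physician_id = character(), I0 = numeric(),
                      I1 = numeric(), IOBS = numeric(),
                      IeverOBS = integer(), Ipresc2mr = numeric(),
                      Idepresc2mr = numeric(), n_transitions = numeric()))
  }
  rows <- lapply(names(ptrcms), function(k) {
    m <- ptrcms[[k]]
    data.table(
      physician_id = k,
      I0 = index_alpha(m, 0),
      I1 = index_alpha(m, 1),
      IOBS = index_obs(m),
      IeverOBS = ever_obs(m),
      Ipresc2mr = two_or_more(m, "prescribing"),
      Idepresc2mr = two_or_more(m, "deprescribing"),
      n_transitions = sum(m[upper.tri(m)]) + sum(m[lower.tri(m)])
    )
  })
  rbindlist(rows)[]
}

#' Summarize prescribing indexes by physician group
#'
#' Per-group arithmetic mean and standard error (`sd / sqrt(n)`) of each
#' index, computed over physicians with a defined (non-`NA`) value only.
#'
#' @param profiles Output of [prescribing_profiles()].
#' @param grouping Named character vector mapping `physician_id` to a group
#'   label (e.g. specialty), or a data frame with columns `physician_id`
#'   and `group`.
#' @param indexes Which index columns to summarize.
#' @return `data.table` with columns `group`, `index`, `mean`, `se`, `n`.
#'   `se` is `NA` for singleton groups.
#' @export
summarize_by_group <- function(profiles, grouping,
                               indexes = c("I0", "I1", "IOBS", "IeverOBS",
                                           "Ipresc2mr", "Idepresc2mr")) {
  pr <- as.data.table(profiles)
  if (is.data.frame(grouping)) {
    gmap <- setNames(as.character(grouping$group),
                     as.character(grouping$physician_id))
  } else {
    gmap <- grouping
  }
  pr[, group := unname(gmap[as.character(physician_id)])]
  pr[, (indexes) := lapply(.SD, as.numeric), .SDcols = indexes]
  long <- melt(pr[, c("physician_id", "group", indexes), with = FALSE],
               id.vars = c("physician_id", "group"),
               variable.name = "index", value.name = "value",
               variable.factor = FALSE)
  long <- long[!is.na(value) & !is.na(group)]
  long[, .(mean = mean(value),
           se = if (.N > 1L) sd(value) / sqrt(.N) else NA_real_,
           n = .N),
       by = .(group, index)][]
}
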