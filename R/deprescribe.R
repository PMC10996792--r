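# Heuristic identification and attribution of deprescribing events.
#
# Deprescribing leaves no claim of its own: it is inferred from a long
# prescription that is never refilled, attributed to the physician(s) the
# patient saw most recently before the supply ran out, provided that visit
# fell within a qualifying window before the exposure end.

#' Exposures eligible as deprescribing targets
#'
#' Keeps merged exposures longer than `min_length` days with no subsequent
#' exposure of the same drug for the same patient within the year. Because
#' refill merging has already absorbed temporary gaps, a later same-drug
#' exposure means the prescription was refilled, not discontinued.
#'
#' @param exposures Output of [merge_refills()].
#' @param min_length Minimum exposure length in days, strict (default 30:
#'   exposures of exactly 30 days are excluded as likely acute scripts).
#' @return `data.table` of eligible exposures (same columns as input).
#' @export
eligible_targets <- function(exposures, min_length = 30L) {
  ex <- as.data.table(exposures)
  if (nrow(ex) == 0L) return(ex)
  # a later same-drug episode (of any length) means a refill, not a stop
  ex[, last_start := max(start_day), by = .(patient_id, drug_id)]
  out <- ex[start_day == last_start & (end_day - start_day) > min_length]
  out[, last_start := NULL]
  ex[, last_start := NULL]
  out[]
}

#' Attribute deprescribing transitions to candidate physicians
#'
#' For each eligible target exposure, the candidate visit is the patient's
#' latest encounter strictly before the exposure's end day; attribution
#' requires the discontinuation to occur within `max_gap` days (inclusive)
#' of that visit. All physicians seen on the candidate day are
#' co-responsible with equal weights. State transitions are emitted at
#' every pure-loss interval boundary (at least one class ends, none
#' starts); when several ended drugs share a boundary their qualifying
#' candidates pool into one responsible set with equal weights. Boundaries
#' with no qualifying visit are emitted with empty responsibility (they
#' shape the patient trajectory but enter no physician's responsibility
#' matrix).
#'
#' @param targets Output of [eligible_targets()].
#' @param encounters Data frame with `patient_id`, `physician_id`, `day`.
#' @param intervals Output of [segment_intervals()] for the same patients.
#' @param max_gap Maximum days (inclusive) between candidate visit and
#'   exposure end (default 30).
#' @return List with `transitions` (long format as in
#'   [extract_prescribing_transitions()], direction `"deprescribing"`,
#'   `physician_id` `NA` when unattributed) and `targets` (per-target
#'   attribution: candidate visit day, qualification flag, candidates).
#' @export
attribute_deprescribing <- function(targets, encounters, intervals,
                                    max_gap = 30L) {
  tg <- as.data.table(targets)
  en <- as.data.table(encounters)
  en[, `:=`(patient_id = as.character(patient_id),
            physician_id = as.character(physician_id))]

  # per-target candidate visit and qualification
  if (nrow(tg) > 0L) {
    tg[, patient_id := as.character(patient_id)]
    cand <- lapply(seq_len(nrow(tg)), function(r) {
      pid <- tg$patient_id[r]; ed <- tg$end_day[r]
      days <- en[patient_id == pid & day < ed, day]
      if (length(days) == 0L) {
        return(list(visit_day = NA_integer_, qualified = FALSE,
                    candidates = list(character(0))))
      }
      vd <- max(days)
      q <- (ed - vd) <= max_gap
      cands <- if (q) sort(unique(en[patient_id == pid & day == vd,
                                     physician_id])) else character(0)
      list(visit_day = as.integer(vd), qualified = q,
           candidates = list(cands))
    })
    tg[, visit_day := vapply(cand, `[[`, integer(1), "visit_day")]
    tg[, qualified := vapply(cand, `[[`, logical(1), "qualified")]
    tg[, candidates := lapply(cand, function(z) z$candidates[[1]])]
  } else {
    tg[, `:=`(visit_day = integer(0), qualified = logical(0),
              candidates = list())]
  }

  # pure-loss state boundaries: classes lost, none gained
  tx <- state_transitions(intervals)
  long_empty <- data.table(patient_id = character(), occasion = integer(),
                           day = integer(), from_state = integer(),
                           to_state = integer(), direction = character(),
                           physician_id = character(), weight = numeric(),
                           n_responsible = integer())
  if (nrow(tx) == 0L) return(list(transitions = long_empty, targets = tg[]))
  pure_loss <- mapply(function(f, t) {
    fc <- strsplit(STATE_KEYS[f], "")[[1]]
    tc <- strsplit(STATE_KEYS[t], "")[[1]]
    length(setdiff(fc, tc)) > 0L && length(setdiff(tc, fc)) == 0L
  }, tx$from_state, tx$to_state)
  tx <- tx[pure_loss]
  if (nrow(tx) == 0L) return(list(transitions = long_empty, targets = tg[]))
  tx[, direction := "deprescribing"]

  rows <- lapply(seq_len(nrow(tx)), function(r) {
    pid <- tx$patient_id[r]; d <- tx$day[r]
    hit <- tg[patient_id == pid & end_day == d & qualified == TRUE]
    pool <- sort(unique(unlist(hit$candidates)))
    n <- length(pool)
    if (n == 0L) {
      cbind(tx[r], data.table(physician_id = NA_character_,
                              weight = NA_real_, n_responsible = 0L))
    } else {
      cbind(tx[r][rep(1L, n)],
            data.table(physician_id = pool, weight = 1 / n,
                       n_responsible = n))
    }
  })
  out <- rbindlist(rows)
  setcolorder(out, c("patient_id", "occasion", "day", "from_state",
                     "to_state", "direction", "physician_id", "weight",
                     "n_responsible"))
  list(transitions = out[], targets = tg[])
}

#' Combine prescribing and deprescribing transition tables
#'
#' @param presc Long transition table from
#'   [extract_prescribing_transitions()].
#' @param depresc Long transition table (`$transitions`) from
#'   [attribute_deprescribing()].
#' @return A single long transition table ordered by patient and occasion.
#' @export
combine_transitions <- function(presc, depresc) {
  out <- rbindlist(list(as.data.table(presc), as.data.table(depresc)),
                   use.names = TRUE)
  setorder(out, patient_id, occasion, physician_id, na.last = TRUE)
  out[]
}

#' Diagnostics for deprescribing attribution
#'
#' @param attribution Result of [attribute_deprescribing()].
#' @return One-row `data.table`: number of eligible targets, how many had a
#'   qualifying visit, how many deprescribing transitions were emitted and
#'   how many of those carry responsibility.
#' @export
deprescribing_diagnostics <- function(attribution) {
  tg <- attribution$targets
  tx <- attribution$transitions
  ev <- unique(tx[, .(patient_id, occasion, n_responsible)])
  data.table(
    n_eligible = nrow(tg),
    n_qualified = sum(tg$qualified),
    n_transitions = nrow(ev),
    n_attributed = sum(ev$n_responsible > 0L)
  )
}
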