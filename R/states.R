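# Prescription drug classes and the 8-state space over their subsets.
#
# States are numbered 1..8 in the order: zero, O, B, S, OB, OS, BS, OBS.
# The tier structure (no drugs / one class / two classes / all three) is
# what every downstream index depends on; the within-tier order is a fixed
# convention.

DRUG_CLASSES <- c("O", "B", "S")

STATE_KEYS <- c("", "O", "B", "S", "OB", "OS", "BS", "OBS")

STATE_LABELS <- c("zero", "O", "B", "S", "OB", "OS", "BS", "OBS")

STATE_DRUG_COUNT <- c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L)

#' Canonical key for a set of drug classes
#'
#' Collapses a subset of `c("O", "B", "S")` into the canonical key used to
#' label prescription states (classes sorted in O, B, S order, duplicates
#' removed). The empty set maps to `""`.
#'
#' @param classes Character vector of drug classes (a subset of
#'   `c("O", "B", "S")`, possibly with repeats).
#' @return A single string, e.g. `"OB"`.
#' @export
class_key <- function(classes) {
  classes <- unique(classes)
  classes <- classes[!is.na(classes) & nzchar(classes)]
  if (length(classes) == 0L) return("")
  bad <- setdiff(classes, DRUG_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown drug class(es): ", paste(bad, collapse = ", "))
  }
  paste(DRUG_CLASSES[DRUG_CLASSES %in% classes], collapse = "")
}

#' Classify a set of active drug classes into a prescription state
#'
#' Maps a subset of the three monitored drug classes (opioids `O`,
#' benzodiazepines `B`, sedative-hypnotics `S`) to its prescription state
#' number: 1 = no drugs, 2-4 = exactly one class (O, B, S), 5-7 = two
#' classes concurrently (OB, OS, BS), 8 = all three concurrently.
#'
#' @param classes Character vector giving the active classes of one state
#'   (e.g. `c("O", "B")`), or a canonical key string such as `"OB"`.
#' @return Integer state in 1..8.
#' @seealso [drug_count()], [state_from_key()]
#' @export
classify_state <- function(classes) {
  state_from_key(class_key(classes))
}

#' Vectorized state lookup from canonical class keys
#'
#' @param keys Character vector of canonical class keys (see [class_key()]).
#' @return Integer vector of states in 1..8.
#' @export
state_from_key <- function(keys) {
  st <- match(keys, STATE_KEYS)
  if (anyNA(st)) {
    stop("non-canonical class key(s): ",
         paste(unique(keys[is.na(st)]), collapse = ", "))
  }
  st
}

#' Number of drug classes active in a prescription state
#'
#' @param state Integer vector of states in 1..8.
#' @return Integer vector: 0 for state 1, 1 for states 2-4, 2 for states
#'   5-7, 3 for state 8.
#' @export
drug_count <- function(state) {
  if (any(state < 1L | state > 8L | state != as.integer(state))) {
    stop("states must be integers in 1..8")
  }
  STATE_DRUG_COUNT[state]
}

#' Merge refill chains of prescription fills into exposure episodes
#'
#' Scans each patient's fills of the same drug chronologically and joins a
#' subsequent fill to the ongoing exposure when it starts no later than the
#' current exposure end plus a buffer of `gap_fraction` times the preceding
#' fill's days supply (default 20%). Overlapping fills always merge. A
#' merged exposure keeps the physician who initiated it, regardless of who
#' signed later refills; a fill beyond the buffer starts a new exposure.
#'
#' @param fills Data frame of prescription fills with columns `patient_id`,
#'   `prescriber_id`, `drug_id`, `drug_class`, `start_day`, `days_supply`.
#' @param gap_fraction Buffer as a fraction of the preceding fill's days
#'   supply (default `0.2`).
#' @return A `data.table` of exposures with columns `patient_id`, `drug_id`,
#'   `drug_class`, `start_day`, `end_day` (half-open, exclusive),
#'   `initiating_physician` and `n_fills`.
#' @export
merge_refills <- function(fills, gap_fraction = 0.2) {
  ft <- as.data.table(fills)
  need <- c("patient_id", "prescriber_id", "drug_id", "drug_class",
            "start_day", "days_supply")
  miss <- setdiff(need, names(ft))
  if (length(miss) > 0L) stop("fills missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(ft) == 0L) {
    return(data.table(patient_id = character(), drug_id = character(),
                      drug_class = character(), start_day = integer(),
                      end_day = integer(), initiating_physician = character(),
                      n_fills = integer()))
  }
  if (any(ft$days_supply < 1)) stop("days_supply must be >= 1")
  setorder(ft, patient_id, drug_id, start_day, prescriber_id)
  out <- ft[, merge_one_chain(start_day, days_supply, prescriber_id, gap_fraction),
            by = .(patient_id, drug_id, drug_class)]
  setcolorder(out, c("patient_id", "drug_id", "drug_class", "start_day",
                     "end_day", "initiating_physician", "n_fills"))
  out[]
}

merge_one_chain <- function(starts, supplies, prescribers, gap_fraction) {
  n <- length(starts)
  o_start <- integer(0); o_end <- integer(0); o_phys <- character(0); o_n <- integer(0)
  cur_start <- starts[1L]
  cur_end <- starts[1L] + supplies[1L]
  cur_phys <- prescribers[1L]
  cur_n <- 1L
  prev_supply <- supplies[1L]
  if (n > 1L) {
    for (r in 2:n) {
      if (starts[r] <= cur_end + gap_fraction * prev_supply) {
        cur_end <- max(cur_end, starts[r] + supplies[r])
        cur_n <- cur_n + 1L
      } else {
        o_start <- c(o_start, cur_start); o_end <- c(o_end, cur_end)
        o_phys <- c(o_phys, cur_phys); o_n <- c(o_n, cur_n)
        cur_start <- starts[r]
        cur_end <- starts[r] + supplies[r]
        cur_phys <- prescribers[r]
        cur_n <- 1L
      }
      prev_supply <- supplies[r]
    }
  }
  list(start_day = c(o_start, cur_start),
       end_day = as.integer(c(o_end, cur_end)),
       initiating_physician = c(o_phys, cur_phys),
       n_fills = c(o_n, cur_n))
}

#' Segment merged exposures into contiguous prescription-state intervals
#'
#' Splits each patient's study year into half-open intervals at every
#' exposure start and end, labels each interval with the set of drug
#' classes active during it and the corresponding prescription state, and
#' coalesces adjacent intervals sharing the same state. Leading and
#' trailing drug-free periods are labeled state 1 ("zero"). Intervals tile
#' `[0, year_end)` exactly for every patient present.
#'
#' @param exposures Output of [merge_refills()].
#' @param patients Optional vector of patient ids to include even when they
#'   have no exposures (they get a single all-year state-1 interval).
#' @param year_end Length of the study year in days (default 365).
#' @return `data.table` with columns `patient_id`, `start_day`, `end_day`,
#'   `classes` (canonical key) and `state`.
#' @export
segment_intervals <- function(exposures, patients = NULL, year_end = 365L) {
  ex <- as.data.table(exposures)
  ids <- unique(c(as.character(ex$patient_id), as.character(patients)))
  if (length(ids) == 0L) {
    return(data.table(patient_id = character(), start_day = integer(),
                      end_day = integer(), classes = character(),
                      state = integer()))
  }
  pieces <- lapply(ids, function(pid) {
    sub <- ex[patient_id == pid]
    seg <- segment_one(sub$start_day, sub$end_day, sub$drug_class, year_end)
    data.table(patient_id = pid, start_day = seg$start, end_day = seg$end,
               classes = seg$key, state = seg$state)
  })
  rbindlist(pieces)[]
}

segment_one <- function(starts, ends, classes, year_end) {
  starts <- pmin(pmax(starts, 0L), year_end)
  ends <- pmin(pmax(ends, 0L), year_end)
  bp <- sort(unique(c(0L, starts, ends, as.integer(year_end))))
  s <- bp[-length(bp)]
  e <- bp[-1L]
  key <- vapply(s, function(t) {
    class_key(classes[starts <= t & ends > t])
  }, character(1))
  # coalesce adjacent intervals with identical state
  r <- rle(key)
  idx_end <- cumsum(r$lengths)
  idx_start <- c(1L, head(idx_end, -1L) + 1L)
  list(start = s[idx_start], end = e[idx_end], key = r$values,
       state = state_from_key(r$values))
}

#' Skeleton of all prescription-state transitions per patient
#'
#' Turns each patient's interval sequence into the list of state changes:
#' one row per interval boundary where the state changes, carrying the
#' boundary day, the states either side, an occasion index (chronological
#' per patient) and the direction implied by the state numbering
#' (transitions to a higher-numbered state sit above the diagonal of the
#' transition matrix and count as prescribing; below, deprescribing).
#'
#' @param intervals Output of [segment_intervals()].
#' @return `data.table` with columns `patient_id`, `occasion`, `day`,
#'   `from_state`, `to_state`, `direction`.
#' @export
state_transitions <- function(intervals) {
  iv <- as.data.table(intervals)
  if (nrow(iv) == 0L) {
    return(data.table(patient_id = character(), occasion = integer(),
                      day = integer(), from_state = integer(),
                      to_state = integer(), direction = character()))
  }
  setorder(iv, patient_id, start_day)
  tx <- iv[, {
    k <- .N
    if (k < 2L) {
      list(occasion = integer(0), day = integer(0),
           from_state = integer(0), to_state = integer(0))
    } else {
      list(occasion = seq_len(k - 1L), day = start_day[-1L],
           from_state = state[-k], to_state = state[-1L])
    }
  }, by = patient_id]
  tx[, direction := ifelse(to_state > from_state, "prescribing", "deprescribing")]
  tx[]
}

#' Extract prescribing transitions with responsible physicians
#'
#' At every interval boundary where the patient's active class set gains at
#' least one drug class, the transition is attributed to the physician(s)
#' who initiated the exposure(s) starting on that day. When several
#' distinct physicians initiate on the same day they share responsibility
#' with equal weights summing to one.
#'
#' @param intervals Output of [segment_intervals()].
#' @param exposures Output of [merge_refills()].
#' @return `data.table` in long transition format: `patient_id`, `occasion`,
#'   `day`, `from_state`, `to_state`, `direction`, `physician_id`, `weight`,
#'   `n_responsible` (one row per responsible physician).
#' @export
extract_prescribing_transitions <- function(intervals, exposures) {
  tx <- state_transitions(intervals)
  ex <- as.data.table(exposures)
  empty <- data.table(patient_id = character(), occasion = integer(),
                      day = integer(), from_state = integer(),
                      to_state = integer(), direction = character(),
                      physician_id = character(), weight = numeric(),
                      n_responsible = integer())
  if (nrow(tx) == 0L) return(empty)
  gained <- mapply(function(f, t) {
    length(setdiff(strsplit(STATE_KEYS[t], "")[[1]],
                   strsplit(STATE_KEYS[f], "")[[1]])) > 0L
  }, tx$from_state, tx$to_state)
  tx <- tx[gained]
  if (nrow(tx) == 0L) return(empty)
  starters <- ex[, .(patient_id = as.character(patient_id),
                     day = start_day,
                     physician_id = as.character(initiating_physician))]
  starters <- unique(starters)
  out <- merge(tx, starters, by = c("patient_id", "day"),
               all.x = TRUE, allow.cartesian = TRUE)
  out[, n_responsible := sum(!is.na(physician_id)),
      by = .(patient_id, occasion)]
  out[, weight := ifelse(n_responsible > 0L, 1 / n_responsible, NA_real_)]
  setcolorder(out, c("patient_id", "occasion", "day", "from_state",
                     "to_state", "direction", "physician_id", "weight",
                     "n_responsible"))
  setorder(out, patient_id, occasion, physician_id)
  out[]
}
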