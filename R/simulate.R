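# Synthetic claims generator.
#
# Emulates the statistical structure the analysis assumes on a one-year
# (365-day) calendar: prescription fills with refill chains inside the
# 20% merge buffer, multi-class concurrent exposure that intensifies
# with a physician's latent risky-prescribing propensity, planted
# deprescribing events (a clinical visit shortly before a long exposure
# ends, with no refill thereafter), and patient-sharing that is
# assortative on the latent propensity so the downstream homophily
# machinery has a recoverable signal. Ground truth (latent risks,
# planted deprescribing events) is returned separately for validation.

#' Simulation configuration
#'
#' @param n_physicians,n_patients,n_regions Population sizes.
#' @param specialty_probs Named probability vector over specialties
#'   (must sum to 1 within 1e-9).
#' @param homophily_strength Nonnegative scale of the assortativity of
#'   patient-sharing on the physicians' latent risky-prescribing
#'   propensity: a patient's additional physicians are drawn with weights
#'   `exp(-homophily_strength * |risk difference from their primary
#'   physician|)`. 0 disables the planted homophily.
#' @param refill_rate Probability that a fill is followed by another
#'   refill within the merge buffer.
#' @param risky_escalation_rate Baseline probability scale for a
#'   prescribing physician adding a concurrent fill of another drug
#'   class (multiplied by the physician's latent risk).
#' @param deprescribe_rate Fraction of qualifying long exposures that end
#'   with a planted deprescribing visit.
#' @param products_per_class Distinct drug products per class.
#' @param visits_per_pair Mean routine encounters per patient-physician
#'   pair.
#' @param physicians_per_patient Mean panel size per patient (at least 2).
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration.
#' @return Object of class `rx_sim_config` (a validated list).
#' @export
sim_config <- function(n_physicians = 150L, n_patients = 600L,
                       n_regions = 4L,
                       specialty_probs = c(primary_care = 0.40,
                                           emergency_medicine = 0.15,
                                           neurology = 0.10,
                                           psychiatry = 0.10,
                                           other = 0.25),
                       homophily_strength = 2,
                       refill_rate = 0.6,
                       risky_escalation_rate = 0.5,
                       deprescribe_rate = 0.4,
                       products_per_class = 3L,
                       visits_per_pair = 1.5,
                       physicians_per_patient = 3,
                       seed = 1L) {
  cfg <- list(n_physicians = as.integer(n_physicians),
              n_patients = as.integer(n_patients),
              n_regions = as.integer(n_regions),
              specialty_probs = specialty_probs,
              homophily_strength = homophily_strength,
              refill_rate = refill_rate,
              risky_escalation_rate = risky_escalation_rate,
              deprescribe_rate = deprescribe_rate,
              products_per_class = as.integer(products_per_class),
              visits_per_pair = visits_per_pair,
              physicians_per_patient = physicians_per_patient,
              seed = as.integer(seed))
  if (any(c(cfg$n_physicians, cfg$n_patients, cfg$n_regions,
            cfg$products_per_class) < 1L)) {
    stop("population sizes must be positive")
  }
  if (abs(sum(cfg$specialty_probs) - 1) > 1e-9 ||
      any(cfg$specialty_probs < 0) || is.null(names(cfg$specialty_probs))) {
    stop("specialty_probs must be a named nonnegative vector summing to 1")
  }
  rates <- c(cfg$refill_rate, cfg$risky_escalation_rate,
             cfg$deprescribe_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$homophily_strength < 0) {
    stop("homophily_strength must be nonnegative")
  }
  if (cfg$physicians_per_patient < 2) {
    stop("physicians_per_patient must be at least 2")
  }
  structure(cfg, class = "rx_sim_config")
}

#' Generate a synthetic claims cohort
#'
#' See [sim_config()] for the generator's knobs. Every fill's start day
#' coincides with an encounter between the patient and the prescriber on
#' that day; planted deprescribing events are guaranteed to have a
#' qualifying candidate visit (the patient's last contact before the
#' supply lapses) so attribution sensitivity can be validated against
#' ground truth.
#'
#' @param config An `rx_sim_config`.
#' @return Object of class `rx_cohort`: list with `fills`, `encounters`,
#'   `physicians`, `patients` tables, `truth` (list with `deprescribing`
#'   ground-truth table) and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "rx_sim_config"))
  set.seed(config$seed)
  P <- config$n_physicians
  N <- config$n_patients
  R <- config$n_regions

  physicians <- data.table(
    physician_id = sprintf("phy%04d", seq_len(P)),
    specialty = sample(names(config$specialty_probs), P, replace = TRUE,
                       prob = config$specialty_probs),
    region = sprintf("R%02d", sample.int(R, P, replace = TRUE)),
    latent_risk = rbeta(P, 2, 5)
  )
  patients <- data.table(
    patient_id = sprintf("pat%05d", seq_len(N)),
    region = sprintf("R%02d", sample.int(R, N, replace = TRUE))
  )

  # patient panels: a primary physician (region-weighted) plus extras
  # drawn assortatively on the primary's latent risk
  risk <- physicians$latent_risk
  panels <- vector("list", N)
  for (h in seq_len(N)) {
    w_reg <- ifelse(physicians$region == patients$region[h], 1, 0.25)
    primary <- sample.int(P, 1L, prob = w_reg)
    k_extra <- 1L + rpois(1L, max(config$physicians_per_patient - 2, 0))
    k_extra <- min(k_extra, P - 1L)
    w <- exp(-config$homophily_strength * abs(risk - risk[primary])) * w_reg
    w[primary] <- 0
    extra <- sample.int(P, k_extra, prob = w)
    panels[[h]] <- c(primary, extra)
  }

  # routine encounters
  enc_pat <- integer(0); enc_phy <- integer(0); enc_day <- integer(0)
  for (h in seq_len(N)) {
    for (k in panels[[h]]) {
      nv <- 1L + rpois(1L, max(config$visits_per_pair - 1, 0))
      dd <- sample.int(365L, nv, replace = TRUE) - 1L
      enc_pat <- c(enc_pat, rep(h, nv))
      enc_phy <- c(enc_phy, rep(k, nv))
      enc_day <- c(enc_day, dd)
    }
  }
  routine <- data.table(patient = enc_pat, physician = enc_phy,
                        day = enc_day)

  # prescription episodes: per patient-physician pair, possibly with a
  # concurrent second/third class for high-risk physicians, then refill
  # chains inside the merge buffer
  class_probs <- c(O = 0.45, B = 0.30, S = 0.25)
  fills <- list()
  episodes <- list()  # one row per (patient, drug) chain, for planting
  for (h in seq_len(N)) {
    used_drugs <- character(0)
    for (k in panels[[h]]) {
      if (runif(1) >= 0.15 + 0.45 * risk[k]) next
      n_classes <- 1L
      if (runif(1) < config$risky_escalation_rate * risk[k]) {
        n_classes <- 2L
      }
      if (n_classes == 2L &&
          runif(1) < config$risky_escalation_rate * risk[k]) {
        n_classes <- 3L
      }
      cls <- sample(names(class_probs), n_classes, prob = class_probs)
      base_start <- sample.int(300L, 1L) - 1L
      for (ci in seq_along(cls)) {
        avail <- setdiff(paste0(cls[ci], seq_len(config$products_per_class)),
                         used_drugs)
        if (length(avail) == 0L) next
        drug <- if (length(avail) == 1L) avail else sample(avail, 1L)
        used_drugs <- c(used_drugs, drug)
        # escalation classes are co-prescribed at the same visit half
        # the time, otherwise added at a follow-up within 20 days
        start <- base_start + if (ci == 1L || runif(1) < 0.5) 0L else
          sample.int(20L, 1L)
        if (start >= 365L) next
        supply <- sample(c(30L, 60L, 90L), 1L, prob = c(0.5, 0.3, 0.2))
        chain_starts <- start
        chain_phys <- k
        cur_start <- start
        while (runif(1) < config$refill_rate &&
               length(chain_starts) < 4L) {
          gap <- sample(seq(-3L, max(floor(0.2 * supply) - 1L, 0L)), 1L)
          nxt <- cur_start + supply + gap
          if (nxt >= 365L || nxt <= cur_start) break
          signer <- if (runif(1) < 0.8) k else sample(panels[[h]], 1L)
          chain_starts <- c(chain_starts, nxt)
          chain_phys <- c(chain_phys, signer)
          cur_start <- nxt
        }
        fills[[length(fills) + 1L]] <- data.table(
          patient = h, prescriber = chain_phys, drug_id = drug,
          drug_class = cls[ci], start_day = chain_starts,
          days_supply = supply)
        episodes[[length(episodes) + 1L]] <- data.table(
          patient = h, drug_id = drug,
          first_start = start,
          end_day = cur_start + supply,
          initiator = k)
      }
    }
  }
  fills <- if (length(fills) > 0L) rbindlist(fills) else
    data.table(patient = integer(0), prescriber = integer(0),
               drug_id = character(0), drug_class = character(0),
               start_day = integer(0), days_supply = integer(0))
  episodes <- if (length(episodes) > 0L) rbindlist(episodes) else
    data.table(patient = integer(0), drug_id = character(0),
               first_start = integer(0), end_day = integer(0),
               initiator = integer(0))

  # plant deprescribing events on long exposures ending inside the year:
  # a visit 3-10 days before the supply lapses, as the patient's final
  # contact in that window, with no refill thereafter (the chain already
  # ended)
  truth <- list()
  planted <- data.table(patient = integer(0), day = integer(0),
                        end = integer(0))
  drop_routine <- rep(FALSE, nrow(routine))
  if (nrow(episodes) > 0L) {
    cand <- which(episodes$end_day - episodes$first_start > 40L &
                    episodes$end_day <= 350L)
    for (e in cand) {
      if (runif(1) >= config$deprescribe_rate) next
      h <- episodes$patient[e]
      ed <- episodes$end_day[e]
      vd <- ed - sample(3:10, 1L)
      # a same-patient fill starting in (vd, ed) would override the
      # candidate visit: skip planting
      f_h <- fills[patient == h & start_day > vd & start_day < ed]
      if (nrow(f_h) > 0L) next
      p_h <- planted[patient == h]
      if (nrow(p_h) > 0L &&
          any((p_h$day > vd & p_h$day < ed) | (vd > p_h$day & vd < p_h$end))) {
        next
      }
      depr <- sample(panels[[h]], 1L)
      drop_routine <- drop_routine |
        (routine$patient == h & routine$day > vd & routine$day < ed)
      routine <- rbind(routine,
                       data.table(patient = h, physician = depr, day = vd))
      drop_routine <- c(drop_routine, FALSE)
      planted <- rbind(planted,
                       data.table(patient = h, day = vd, end = ed))
      truth[[length(truth) + 1L]] <- data.table(
        patient = h, drug_id = episodes$drug_id[e], end_day = ed,
        physician = depr, visit_day = vd)
    }
  }
  routine <- routine[!drop_routine]
  truth <- if (length(truth) > 0L) rbindlist(truth) else
    data.table(patient = integer(0), drug_id = character(0),
               end_day = integer(0), physician = integer(0),
               visit_day = integer(0))

  pid <- patients$patient_id
  kid <- physicians$physician_id
  fill_enc <- unique(fills[, .(patient, physician = prescriber,
                               day = start_day)])
  encounters <- unique(rbind(routine, fill_enc))
  encounters <- data.table(patient_id = pid[encounters$patient],
                           physician_id = kid[encounters$physician],
                           day = encounters$day)
  setorder(encounters, patient_id, day, physician_id)

  fills_out <- data.table(patient_id = pid[fills$patient],
                          prescriber_id = kid[fills$prescriber],
                          drug_id = fills$drug_id,
                          drug_class = fills$drug_class,
                          start_day = fills$start_day,
                          days_supply = fills$days_supply)
  setorder(fills_out, patient_id, drug_id, start_day)

  truth_out <- data.table(patient_id = pid[truth$patient],
                          drug_id = truth$drug_id,
                          end_day = truth$end_day,
                          physician_id = kid[truth$physician],
                          visit_day = truth$visit_day)

  structure(list(fills = fills_out, encounters = encounters,
                 physicians = physicians, patients = patients,
                 truth = list(deprescribing = truth_out),
                 config = config),
            class = "rx_cohort")
}

#' @export
print.rx_cohort <- function(x, ...) {
  cat("<rx_cohort> ", nrow(x$physicians), " physicians, ",
      nrow(x$patients), " patients, ", nrow(x$fills), " fills, ",
      nrow(x$encounters), " encounters, ",
      nrow(x$truth$deprescribing), " planted deprescribing events\n",
      sep = "")
  invisible(x)
}
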