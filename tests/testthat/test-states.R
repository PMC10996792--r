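test_that("state classification enumerates the 8 subsets of {O,B,S}", {
  subsets <- list(character(0), "O", "B", "S", c("O", "B"), c("O", "S"),
                  c("B", "S"), c("O", "B", "S"))
  states <- vapply(subsets, classify_state, integer(1))
  expect_identical(states, 1:8)
  # drug_count(classify_state(C)) = |C| for every subset
  expect_identical(drug_count(states),
                   vapply(subsets, length, integer(1)))
  # order inside a set never matters
  expect_identical(classify_state(c("S", "O")), classify_state(c("O", "S")))
  expect_error(classify_state("X"), "unknown drug class")
  expect_error(drug_count(9L), "1..8")
})

test_that("refill merging follows the 20% buffer arithmetic", {
  # gap 3 < 6 = 0.2 * 30: one exposure [0, 63)
  m <- merge_refills(make_fills("p", "k", "O1", "O", c(0, 33), c(30, 30)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start_day, m$end_day), c(0L, 63L))
  # gap 7 > 6: two exposures
  m2 <- merge_refills(make_fills("p", "k", "O1", "O", c(0, 37), c(30, 30)))
  expect_equal(nrow(m2), 2L)
  # boundary: start exactly at end + buffer still merges
  m3 <- merge_refills(make_fills("p", "k", "O1", "O", c(0, 36), c(30, 30)))
  expect_equal(nrow(m3), 1L)
  # overlapping fills always merge and keep the max end
  m4 <- merge_refills(make_fills("p", "k", "O1", "O", c(0, 20), c(30, 30)))
  expect_equal(c(m4$start_day, m4$end_day), c(0L, 50L))
  # a refill signed by another physician still merges and keeps the
  # initiating physician
  m5 <- merge_refills(make_fills("p", c("k1", "k2"), "O1", "O",
                                 c(0, 25), c(30, 30)))
  expect_equal(nrow(m5), 1L)
  expect_equal(m5$initiating_physician, "k1")
  # the buffer uses the preceding fill's supply, not the exposure length
  m6 <- merge_refills(make_fills("p", "k", "O1", "O",
                                 c(0, 25, 62), c(30, 10, 10)))
  # second fill: [25, 35) merged; buffer after it is 0.2*10 = 2, so a
  # fill at 62 (gap 27 from end 35) starts a new exposure
  expect_equal(nrow(m6), 2L)
  expect_error(merge_refills(make_fills("p", "k", "O1", "O", 0, 0)),
               "days_supply")
})

test_that("re-merging merged exposures is a coarsening fixed point", {
  # the buffer is 20% of the preceding FILL's supply, so re-merging
  # exposures rendered back as single long fills can only ever join
  # exposures, never split or shift them
  set.seed(42)
  fills <- data.frame(
    patient_id = sample(paste0("p", 1:5), 60, TRUE),
    prescriber_id = sample(paste0("k", 1:4), 60, TRUE),
    drug_id = sample(c("O1", "B1", "S1"), 60, TRUE),
    start_day = sample(0:330, 60, TRUE),
    days_supply = sample(c(10L, 30L, 60L), 60, TRUE))
  fills$drug_class <- substr(fills$drug_id, 1, 1)
  m1 <- merge_refills(fills)
  back <- data.frame(patient_id = m1$patient_id,
                     prescriber_id = m1$initiating_physician,
                     drug_id = m1$drug_id, drug_class = m1$drug_class,
                     start_day = m1$start_day,
                     days_supply = m1$end_day - m1$start_day)
  m2 <- merge_refills(back)
  expect_lte(nrow(m2), nrow(m1))
  expect_true(all(paste(m2$patient_id, m2$drug_id, m2$start_day) %in%
                    paste(m1$patient_id, m1$drug_id, m1$start_day)))
  # initiating physician of every kept exposure start is preserved
  key1 <- paste(m1$patient_id, m1$drug_id, m1$start_day)
  key2 <- paste(m2$patient_id, m2$drug_id, m2$start_day)
  expect_equal(m2$initiating_physician,
               m1$initiating_physician[match(key2, key1)])
  # and when no merging occurred in the first pass, re-merging is exact
  solo <- data.frame(patient_id = "p", prescriber_id = c("k1", "k2"),
                     drug_id = "O1", drug_class = "O",
                     start_day = c(0L, 100L), days_supply = c(30L, 30L))
  s1 <- merge_refills(solo)
  s_back <- data.frame(patient_id = s1$patient_id,
                       prescriber_id = s1$initiating_physician,
                       drug_id = s1$drug_id, drug_class = s1$drug_class,
                       start_day = s1$start_day,
                       days_supply = s1$end_day - s1$start_day)
  s2 <- merge_refills(s_back)
  expect_equal(s2$start_day, s1$start_day)
  expect_equal(s2$end_day, s1$end_day)
})

test_that("interval segmentation tiles the year and tracks class sets", {
  # single O exposure inside the year: zero / O / zero
  m <- merge_refills(make_fills("p", "k", "O1", "O", 10, 30))
  iv <- segment_intervals(m)
  expect_equal(iv$start_day, c(0L, 10L, 40L))
  expect_equal(iv$end_day, c(10L, 40L, 365L))
  expect_equal(iv$state, c(1L, 2L, 1L))
  # overlapping O and B: O, OB, B then zero
  m2 <- merge_refills(make_fills("p", "k", c("O1", "B1"), c("O", "B"),
                                 c(0, 10), c(30, 40)))
  iv2 <- segment_intervals(m2)
  expect_equal(iv2$classes, c("O", "OB", "B", ""))
  expect_equal(iv2$state, c(2L, 5L, 3L, 1L))
  # no exposures: a single zero interval
  iv3 <- segment_intervals(merge_refills(make_fills("p", "k", "O1", "O", 0, 30)[0, ]),
                           patients = "p")
  expect_equal(nrow(iv3), 1L)
  expect_equal(iv3$state, 1L)
  expect_equal(c(iv3$start_day, iv3$end_day), c(0L, 365L))
})

test_that("interval partition property holds on random exposure sets", {
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(1:6, 1)
    fills <- make_fills("p", "k", paste0(sample(c("O", "B", "S"), k, TRUE),
                                         sample(1:3, k, TRUE)),
                        NA, sample(0:350, k, TRUE), sample(c(7, 30, 90), k, TRUE))
    fills$drug_class <- substr(fills$drug_id, 1, 1)
    iv <- segment_intervals(merge_refills(fills))
    expect_equal(iv$start_day[1], 0L)
    expect_equal(iv$end_day[nrow(iv)], 365L)
    expect_equal(iv$start_day[-1], iv$end_day[-nrow(iv)])
    expect_true(all(iv$end_day > iv$start_day))
    # states consistent with class sets
    expect_equal(iv$state, vapply(strsplit(iv$classes, ""), classify_state,
                                  integer(1)))
  }
})

test_that("prescribing transitions are attributed to initiating physicians", {
  # B-state patient starts O: 3 -> 5 attributed to the opioid prescriber
  m <- merge_refills(make_fills("p", c("kb", "ko"), c("B1", "O1"),
                                c("B", "O"), c(0, 30), c(100, 30)))
  tx <- extract_prescribing_transitions(segment_intervals(m), m)
  row <- tx[tx$from_state == 3L & tx$to_state == 5L, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$physician_id, "ko")
  expect_equal(row$weight, 1)
  # two classes started the same day by two physicians: 1 -> 5, two
  # co-responsible physicians at weight 0.5
  m2 <- merge_refills(make_fills("p", c("k1", "k2"), c("O1", "B1"),
                                 c("O", "B"), c(50, 50), c(30, 30)))
  tx2 <- extract_prescribing_transitions(segment_intervals(m2), m2)
  expect_equal(nrow(tx2), 2L)
  expect_equal(unique(tx2$from_state), 1L)
  expect_equal(unique(tx2$to_state), 5L)
  expect_equal(sort(tx2$physician_id), c("k1", "k2"))
  expect_equal(tx2$weight, c(0.5, 0.5))
  expect_equal(unique(tx2$n_responsible), 2L)
  # a second opioid while already in state O changes nothing
  m3 <- merge_refills(make_fills("p", "k", c("O1", "O2"), "O",
                                 c(10, 20), c(60, 30)))
  tx3 <- extract_prescribing_transitions(segment_intervals(m3), m3)
  expect_equal(tx3$to_state, 2L)  # only the initial 1 -> 2
  expect_equal(nrow(tx3), 1L)
})

test_that("composing transitions reproduces the interval state sequence", {
  set.seed(11)
  for (rep in 1:8) {
    k <- sample(2:7, 1)
    fills <- make_fills("p", paste0("k", sample(1:3, k, TRUE)),
                        paste0(sample(c("O", "B", "S"), k, TRUE),
                               sample(1:2, k, TRUE)),
                        NA, sample(0:320, k, TRUE),
                        sample(c(15, 45, 80), k, TRUE))
    fills$drug_class <- substr(fills$drug_id, 1, 1)
    m <- merge_refills(fills)
    iv <- segment_intervals(m)
    tx <- state_transitions(iv)
    states <- c(iv$state[1], tx$to_state[order(tx$occasion)])
    expect_equal(states, iv$state)
    expect_true(all(tx$from_state != tx$to_state))
    expect_equal(tx$direction == "prescribing", tx$to_state > tx$from_state)
  }
})
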