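test_that("mix reduction reproduces the trial percentages", {
  expect_equal(round(mix_reduction(6702, 1737), 2), 74.08)
  expect_equal(round(mix_reduction(7311, 3011), 2), 58.82)
  expect_equal(mix_reduction(1234, 1234), 0)
  expect_error(mix_reduction(1000, 1100), "exceeds")
})

test_that("product savings are concentration times saved volume", {
  expect_equal(round(ppp_savings(0.20, 6702, 1737), 2), 9.93)
  expect_equal(round(ppp_savings(0.04, 7311, 3011), 2), 1.72)
  expect_equal(round(ppp_savings(0.20, 4905, 3255), 2), 3.30)
  expect_error(ppp_savings(101, 1000, 500), "below 100")
})

test_that("tank counts use a whole-area ceiling", {
  expect_equal(tanks_needed(7311, 1, 2000), 4L)
  expect_equal(tanks_needed(3011, 1, 2000), 2L)
  expect_equal(tanks_needed(2000, 1, 2000), 1L)   # exact fit
  expect_equal(tanks_needed(1, 1, 2000), 1L)      # part-filled tank counts
  # whole-area convention differs from per-ha scaling
  expect_equal(tanks_needed(4905, 10, 1500), 33L)
  expect_false(tanks_needed(4905, 10, 1500) == 10 * tanks_needed(4905, 1, 1500))
})

test_that("tanks over area a at rate v equal tanks over 1 ha at rate v*a", {
  set.seed(5)
  for (i in 1:25) {
    v <- runif(1, 500, 8000)
    a <- sample(1:120, 1)
    cap <- sample(c(1000, 1500, 2000, 3000), 1)
    expect_equal(tanks_needed(v, a, cap), tanks_needed(v * a, 1, cap))
  }
})

test_that("refill time savings match the trial table and track the continuous limit", {
  expect_equal(refill_time_savings(7311, 3011, 2000, 1), 4 / 3)
  expect_equal(round(refill_time_savings(4905, 3255, 1500, 100), 2), 73.33)
  expect_equal(refill_time_savings(3468, 3065, 3000, 1), 0)

  # saved tanks stay within one fill of the continuous difference; the count
  # is not strictly monotone in area (crossing a tank boundary with va but
  # not vc can drop one saved fill), but never goes negative
  set.seed(13)
  for (i in 1:15) {
    va <- runif(1, 500, 5000)
    vc <- va * runif(1, 1, 3)
    cap <- sample(c(1500, 2000, 3000), 1)
    saved_tanks <- vapply(
      1:60, function(a) refill_time_savings(vc, va, cap, a) * 60 / 40,
      numeric(1))
    continuous <- (vc - va) * (1:60) / cap
    expect_true(all(abs(saved_tanks - continuous) < 1))
    expect_true(all(saved_tanks >= 0))
  }
  # concrete non-monotone case: only the adjusted pass crosses a boundary
  expect_equal(refill_time_savings(550, 500, 1000, 2), 40 / 60)
  expect_equal(refill_time_savings(550, 500, 1000, 3), 0)
})

test_that("every published tank and refill-time cell is reproduced", {
  t6 <- load_fixture("T6")
  expect_equal(tanks_needed(t6$vc, 1, t6$tank_capacity), t6$tanks_per_ha_vc)
  expect_equal(tanks_needed(t6$va, 1, t6$tank_capacity), t6$tanks_per_ha_va)
  for (a in c(1, 10, 100)) {
    computed <- refill_time_savings(t6$vc, t6$va, t6$tank_capacity, a)
    printed <- t6[[paste0("savings_h_", a, "ha")]]
    expect_true(all(abs(computed - printed) <= 0.02),
                info = paste("area", a, "ha"))
  }
})

test_that("trial summary flags reported reductions that contradict the volumes", {
  t5 <- load_fixture("T5")
  s <- summarize_trials(t5)
  expect_equal(nrow(s$applications), 14)
  flagged <- s$applications[s$applications$discrepancy, ]
  # two rows in the published table carry reductions inconsistent with their
  # own Vc/Va (probable typos); they are flagged, not corrected
  expect_equal(nrow(flagged), 2)
  expect_setequal(paste(flagged$orchard_id, flagged$date),
                  c("P6 2016-08-12", "P2 2016-09-09"))
  expect_equal(round(flagged$reduction_pct[flagged$orchard_id == "P6"], 2),
               50.93)
  expect_equal(round(flagged$reduction_pct[flagged$orchard_id == "P2"], 2),
               22.99)
})

test_that("trial summary aggregates reductions and ingredient savings", {
  t5 <- load_fixture("T5")
  s <- summarize_trials(t5)
  expect_equal(round(s$overall$mean_reported_reduction_pct, 1), 31.5)
  expect_equal(round(s$overall$min_reduction_pct, 1), 11.6)
  expect_equal(round(s$overall$max_reduction_pct, 2), 74.08)
  expect_equal(nrow(s$ingredients), 36)

  two <- summarize_trials(tibble::tibble(
    orchard_id = c("A", "B"), date = c("d1", "d2"),
    vc = c(1000, 1000), va = c(800, 600)))
  expect_equal(two$overall$mean_reduction_pct, 30)

  one <- summarize_trials(tibble::tibble(
    orchard_id = "A", date = "d1", vc = 1000, va = 800))
  expect_equal(one$overall$mean_reduction_pct,
               one$applications$reduction_pct)
  expect_error(summarize_trials(tibble::tibble()), "non-empty")
})
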