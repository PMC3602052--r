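test_that("weighted stage mean and case-mix mean match the hand oracles", {
  ref <- seer_reference()
  # frozen from the brute-force loop (and exact fractions) on the
  # printed reference table, weights = stage codes 0..5
  expect_equal(stage_weighted_mean(ref), 375428 / 191771, tolerance = 1e-12)
  expect_equal(survival_weighted_case_mix(ref), 16978997.4 / 191771,
               tolerance = 1e-12)

  w_of <- function(s) s
  expect_equal(stage_weighted_mean(ref),
               oracle_stage_weighted_mean(ref$stages$stage,
                                          ref$stages$n_stage,
                                          ref$n_total, w_of),
               tolerance = 1e-12)
  expect_equal(survival_weighted_case_mix(ref),
               oracle_case_mix(ref$stages$n_stage, ref$stages$rel_surv,
                               ref$n_total),
               tolerance = 1e-12)
})

test_that("degenerate inputs fail loudly, never as NaN", {
  ref <- seer_reference()
  st <- ref$stages

  # all mass in stage 0 => zero weighted mean, degenerate as a reference
  st0 <- st
  st0$n_stage <- c(ref$n_total, rep(0, 5))
  zero <- health_object("z", "G", "1999-2003", st0, ref$n_total, 89.1)
  expect_equal(stage_weighted_mean(zero), 0)
  expect_error(essi(ref, zero), "degenerate reference")

  # populated stage without a rate
  stna <- st
  stna$rel_surv[2] <- NA
  broken <- health_object("b", "G", "1999-2003", stna, ref$n_total, 89.1)
  expect_error(survival_weighted_case_mix(broken), "without a survival rate")

  # missing weight for a present stage
  expect_error(stage_weighted_mean(ref, c(`0` = 0, `1` = 1)),
               "no weight for stage")

  # non-positive composite inputs
  expect_error(ope(0, 1, 1), "positive")
  expect_error(ropi(1, -1, 1), "positive")
})

test_that("each index matches a brute-force recomputation on random objects", {
  set.seed(321)
  for (rep in 1:200) {
    stages <- 0:2
    obs <- rand_object("o", stages = stages)
    ref <- rand_object("r", stages = stages)
    w_of <- function(s) s

    expect_equal(essi(obs, ref),
                 oracle_stage_weighted_mean(obs$stages$stage, obs$stages$n_stage,
                                            obs$n_total, w_of) /
                   oracle_stage_weighted_mean(ref$stages$stage, ref$stages$n_stage,
                                              ref$n_total, w_of),
                 tolerance = 1e-12)
    expect_equal(sci(obs, ref),
                 oracle_case_mix(obs$stages$n_stage, obs$stages$rel_surv, obs$n_total) /
                   oracle_case_mix(ref$stages$n_stage, ref$stages$rel_surv, ref$n_total),
                 tolerance = 1e-12)
    expect_equal(swi(obs, ref),
                 oracle_swi(obs$stages$stage, obs$stages$rel_surv, obs$stages$n_stage,
                            ref$stages$stage, ref$stages$rel_surv, ref$stages$n_stage),
                 tolerance = 1e-12)
    expect_equal(sti(obs, ref),
                 (obs$overall_rel_surv / ref$overall_rel_surv) /
                   (oracle_case_mix(obs$stages$n_stage, obs$stages$rel_surv, obs$n_total) /
                      oracle_case_mix(ref$stages$n_stage, ref$stages$rel_surv, ref$n_total)),
                 tolerance = 1e-12)
  }
})

test_that("identity: any object against itself scores ones across the panel", {
  set.seed(11)
  for (rep in 1:50) {
    x <- rand_object("x", stages = 0:5)
    p <- index_panel(x, x)
    expect_equal(unlist(p[, c("essi", "sci", "swi", "sti", "ope", "ropi")]),
                 c(essi = 1, sci = 1, swi = 1, sti = 1, ope = 1, ropi = 1),
                 tolerance = 1e-12)
  }
})

test_that("indices are invariant to count scaling and survival scale", {
  set.seed(22)
  for (rep in 1:200) {
    obs <- rand_object("o")
    ref <- rand_object("r")
    base <- index_panel(obs, ref)
    vals <- function(p) unlist(p[, c("essi", "sci", "swi", "sti", "ope", "ropi")])

    k <- stats::runif(1, 0.1, 10)
    expect_equal(vals(index_panel(scale_counts(obs, k), ref)), vals(base),
                 tolerance = 1e-9)

    frac <- index_panel(as_fraction(obs), as_fraction(ref))
    expect_equal(vals(frac), vals(base), tolerance = 1e-9)
  }
})

test_that("SWI and STI are homogeneous of degree one in the obs rates", {
  set.seed(33)
  for (rep in 1:200) {
    obs <- rand_object("o")
    ref <- rand_object("r")
    c_ <- stats::runif(1, 0.5, 1.1)
    expect_equal(swi(scale_rates(obs, c_stage = c_), ref),
                 c_ * swi(obs, ref), tolerance = 1e-12)
    # scaling only the overall rate scales STI by the same factor
    expect_equal(sti(scale_rates(obs, c_overall = c_), ref),
                 c_ * sti(obs, ref), tolerance = 1e-12)
  }
})

test_that("composite factorizations hold exactly for any valid pair", {
  set.seed(44)
  for (rep in 1:200) {
    p <- index_panel(rand_object("o"), rand_object("r"))
    expect_equal(p$ope, p$sci * p$swi * p$sti, tolerance = 1e-12)
    expect_equal(p$ropi * p$essi, p$swi * p$sti, tolerance = 1e-12)
    expect_equal(p$ope / p$ropi, p$sci * p$essi, tolerance = 1e-12)
  }
})

test_that("eSSI responds monotonically to stage shifts, SWI to rate changes", {
  set.seed(55)
  ref <- rand_object("r")
  for (rep in 1:200) {
    obs <- rand_object("o")
    # ensure a real move happens
    if (obs$stages$n_stage[3] < 10) next
    shifted <- shift_stage_mass(obs, from_stage = 2, to_stage = 1,
                                fraction = 0.5)
    expect_lt(essi(shifted, ref), essi(obs, ref))

    up <- obs
    st <- up$stages
    st$rel_surv[4] <- st$rel_surv[4] * 1.05
    up <- health_object("o", "o", "P1", st, obs$n_total, obs$overall_rel_surv)
    expect_gt(swi(up, ref), swi(obs, ref))
  }
})

test_that("the unknown stage can be excluded from the screening weights", {
  ref <- seer_reference()
  w <- default_stage_weights(include_unknown = FALSE)
  expect_false("5" %in% names(w))
  # dropping the unknown stage from the sum removes its contribution
  expect_error(stage_weighted_mean(ref, w), "no weight for stage")
  st <- ref$stages[ref$stages$stage != 5, ]
  known <- health_object("k", "G", "P", st, ref$n_total, 89.1)
  expect_equal(stage_weighted_mean(known, w),
               (375428 - 5 * 15262) / 191771, tolerance = 1e-12)
})

test_that("SWI averages only over stages represented in both objects", {
  mk <- function(id, stages, rates) {
    n <- rep(10, length(stages))
    health_object(id, id, "P", tibble::tibble(stage = stages, n_stage = n,
                                              rel_surv = rates),
                  sum(n), mean(rates))
  }
  obs <- mk("o", 1:2, c(90, 80))
  ref <- mk("r", 1:3, c(100, 100, 50))
  expect_equal(swi(obs, ref), mean(c(90 / 100, 80 / 100)), tolerance = 1e-12)

  # an empty shared set is an error
  far <- mk("f", 4:5, c(40, 30))
  expect_error(swi(obs, far), "no shared usable stages")

  # stages with zero cases drop out by default but can be kept
  obs0 <- mk("o", 1:3, c(90, 80, 40))
  obs0$stages$n_stage[3] <- 0
  obs0 <- health_object("o", "o", "P", obs0$stages, 20, 85)
  expect_equal(swi(obs0, ref), mean(c(0.9, 0.8)), tolerance = 1e-12)
  expect_equal(swi(obs0, ref, require_cases = FALSE),
               mean(c(0.9, 0.8, 0.8)), tolerance = 1e-12)
})
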