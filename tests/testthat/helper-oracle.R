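# Independent brute-force oracles: straight loop arithmetic on raw
# vectors, sharing no code with the package internals.

oracle_stage_weighted_mean <- function(stage, n, ntot, w_of) {
  acc <- 0
  for (i in seq_along(stage)) acc <- acc + n[i] / ntot * w_of(stage[i])
  acc
}

oracle_case_mix <- function(n, rsr, ntot) {
  acc <- 0
  for (i in seq_along(n)) acc <- acc + n[i] * rsr[i]
  acc / ntot
}

oracle_swi <- function(stage_o, rsr_o, n_o, stage_r, rsr_r, n_r) {
  acc <- 0
  k <- 0
  for (i in seq_along(stage_o)) {
    j <- which(stage_r == stage_o[i])
    if (length(j) == 1 && rsr_r[j] > 0 && n_o[i] > 0 && n_r[j] > 0) {
      acc <- acc + rsr_o[i] / rsr_r[j]
      k <- k + 1
    }
  }
  acc / k
}

# a random valid health object on the given stage codes
rand_object <- function(id = "X", period = "P1", stages = 0:5,
                        group = id, percent = TRUE) {
  n_total <- sample(1000:100000, 1)
  counts <- as.vector(stats::rmultinom(1, n_total,
                                       stats::runif(length(stages), 0.05, 1)))
  rates <- sort(stats::runif(length(stages), 10, 110), decreasing = TRUE)
  overall <- sum(counts * rates) / n_total * stats::runif(1, 0.9, 1.1)
  overall <- min(overall, 119)
  if (!percent) {
    rates <- rates / 100
    overall <- overall / 100
  }
  health_object(id, group, period,
                tibble::tibble(stage = stages, n_stage = counts,
                               rel_surv = rates),
                n_total = n_total, overall_rel_surv = overall)
}

# same stage table, counts scaled by k (proportions unchanged)
scale_counts <- function(obj, k) {
  st <- obj$stages
  st$n_stage <- st$n_stage * k
  health_object(obj$object_id, obj$group, obj$period, st,
                obj$n_total * k, obj$overall_rel_surv)
}

# obs with all stage rates (and optionally overall) scaled by c
scale_rates <- function(obj, c_stage = 1, c_overall = 1) {
  st <- obj$stages
  st$rel_surv <- st$rel_surv * c_stage
  health_object(obj$object_id, obj$group, obj$period, st,
                obj$n_total, obj$overall_rel_surv * c_overall)
}

# percent-scale object re-expressed on the fraction scale
as_fraction <- function(obj) {
  st <- obj$stages
  st$rel_surv <- st$rel_surv / 100
  health_object(obj$object_id, obj$group, obj$period, st,
                obj$n_total, obj$overall_rel_surv / 100)
}

seer_reference <- function() {
  read_long_table(system.file("extdata", "seer17_reference_1999_2003.csv",
                              package = "survbench"))[[1]]
}

seer_panel <- function() {
  readr::read_csv(system.file("extdata", "seer17_panel_1999_2003.csv",
                              package = "survbench"),
                  show_col_types = FALSE)
}
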