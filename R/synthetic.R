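#' Configuration for the synthetic registry generator
#'
#' The generator emulates the shape of real registry summary tables: a
#' small set of ordinal clinical stages (0–4) plus an "unknown" stage,
#' stage counts summing exactly to the total, and stage-specific relative
#' survival declining monotonically from near background-population level
#' at the earliest stages down to low values at metastatic disease, with
#' the unknown stage in between. It makes no claim to reproduce any real
#' registry's numbers — only this qualitative structure.
#'
#' @param n_objects Number of benchmark objects per period.
#' @param periods Character vector of period labels.
#' @param n_total_range Inclusive range the per-object total case count
#'   is drawn from (default 5,000–50,000, a plausible span from district
#'   registries to small national ones).
#' @param stages Stage codes of the stage rows (default 0–5, the last
#'   being "unknown").
#' @param base_probs Baseline stage-distribution probabilities, one per
#'   stage (default mirrors a mammography-era breast-cancer mix: mass
#'   concentrated in stages 1–2, little in-situ and metastatic disease,
#'   a modest unknown share).
#' @param skew Scalar tilting the stage distribution: positive shifts
#'   case mass toward earlier stages (stronger screening), negative
#'   toward later stages. 0 keeps `base_probs`.
#' @param survival_baseline Stage-specific relative survival baseline in
#'   percent, monotone decreasing over clinical stages with the unknown
#'   stage's rate in between (default `c(98, 97, 85, 60, 24, 75)`).
#' @param overall_noise_sd,stage_noise_sd Multiplicative log-normal noise
#'   applied to the overall and stage-specific rates (defaults 0.01 and
#'   0.03); rates are clipped to (0, 120] percent.
#' @param seed Mandatory integer seed; generation is a pure function of
#'   (config, seed).
#' @param group_prefix,id_prefix Label prefixes for generated objects.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_objects = 2, periods = "1999-2003",
                             n_total_range = c(5000, 50000),
                             stages = 0:5,
                             base_probs = c(0.02, 0.40, 0.35, 0.10, 0.05, 0.08),
                             skew = 0,
                             survival_baseline = c(98, 97, 85, 60, 24, 75),
                             overall_noise_sd = 0.01,
                             stage_noise_sd = 0.03,
                             seed,
                             group_prefix = "SYN", id_prefix = "obj") {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(length(stages) >= 1,
            length(base_probs) == length(stages),
            length(survival_baseline) == length(stages),
            all(base_probs > 0), all(survival_baseline > 0),
            n_total_range[1] >= length(stages),
            n_total_range[2] >= n_total_range[1])
  structure(list(n_objects = as.integer(n_objects),
                 periods = as.character(periods),
                 n_total_range = as.integer(n_total_range),
                 stages = as.integer(stages),
                 base_probs = base_probs / sum(base_probs),
                 skew = skew,
                 survival_baseline = survival_baseline,
                 overall_noise_sd = overall_noise_sd,
                 stage_noise_sd = stage_noise_sd,
                 seed = as.integer(seed),
                 group_prefix = group_prefix, id_prefix = id_prefix),
            class = "synthetic_config")
}

# Tilted stage probabilities: exponential tilt by rank, positive skew
# moves mass to early stages.
tilted_probs <- function(cfg) {
  r <- seq_along(cfg$stages) - 1
  p <- cfg$base_probs * exp(-cfg$skew * r)
  p / sum(p)
}

#' Generate synthetic health objects
#'
#' Draws, for each object and period, a total case count, a multinomial
#' stage distribution around the (skew-tilted) baseline probabilities,
#' and stage survival rates around the monotone baseline with truncated
#' multiplicative noise. The overall relative survival is the
#' case-weighted mean of the stage rates times a small noise factor, so
#' generated objects are internally coherent and always pass
#' [validate_objects()]. Deterministic given (config, seed).
#'
#' @param cfg A [synthetic_config()].
#' @return A list of [health_object()]s of length
#'   `n_objects * length(periods)`, ordered object-major.
#' @export
#' @examples
#' objs <- generate_objects(synthetic_config(n_objects = 2, seed = 42))
#' validate_objects(objs) # zero rows
generate_objects <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  probs <- tilted_probs(cfg)
  out <- vector("list", cfg$n_objects * length(cfg$periods))
  k <- 0L
  withr::with_preserve_seed({
  set.seed(cfg$seed)
  for (i in seq_len(cfg$n_objects)) {
    for (p in cfg$periods) {
      n_total <- if (cfg$n_total_range[1] == cfg$n_total_range[2]) {
        cfg$n_total_range[1]
      } else {
        sample(cfg$n_total_range[1]:cfg$n_total_range[2], 1)
      }
      counts <- as.vector(stats::rmultinom(1, n_total, probs))
      noise <- exp(stats::rnorm(length(cfg$stages), 0, cfg$stage_noise_sd))
      rates <- pmin(pmax(cfg$survival_baseline * noise, 0.1), 120)
      overall <- sum(counts * rates) / n_total *
        exp(stats::rnorm(1, 0, cfg$overall_noise_sd))
      overall <- pmin(pmax(overall, 0.1), 120)
      k <- k + 1L
      out[[k]] <- health_object(
        object_id = sprintf("%s%02d", cfg$id_prefix, i),
        group = sprintf("%s%02d", cfg$group_prefix, i),
        period = p,
        stages = tibble::tibble(stage = cfg$stages, n_stage = counts,
                                rel_surv = rates),
        n_total = n_total, overall_rel_surv = overall
      )
    }
  }
  })
  out
}

#' Generate a synthetic registry table in the long CSV format
#'
#' Convenience wrapper: [generate_objects()] followed by
#' [write_long_table()], emitting exactly the format
#' [read_long_table()] consumes.
#'
#' @param cfg A [synthetic_config()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic_table <- function(cfg, path) {
  write_long_table(generate_objects(cfg), path)
}

#' Move case mass between two stages of an object
#'
#' Moves `round(fraction * n_from)` cases from one stage to another,
#' leaving the total unchanged — a controlled stage-shift, the mechanism
#' by which screening programmes skew the case distribution toward
#' earlier stages. Useful as a monotonicity witness: shifting mass to a
#' lower-weight stage strictly lowers the screening index.
#'
#' @param obj A [health_object()].
#' @param from_stage,to_stage Stage codes, both present in `obj`.
#' @param fraction Fraction of the source stage's cases to move, in
#'   (0, 1].
#' @return A new `health_object` with the shifted distribution.
#' @export
shift_stage_mass <- function(obj, from_stage, to_stage, fraction) {
  stopifnot(is_health_object(obj), fraction > 0, fraction <= 1)
  st <- obj$stages
  i <- match(as.integer(from_stage), st$stage)
  j <- match(as.integer(to_stage), st$stage)
  if (is.na(i) || is.na(j)) {
    stop("stage ", if (is.na(i)) from_stage else to_stage,
         " absent from object '", obj$object_id, "'", call. = FALSE)
  }
  moved <- round(fraction * st$n_stage[i])
  st$n_stage[i] <- st$n_stage[i] - moved
  st$n_stage[j] <- st$n_stage[j] + moved
  health_object(obj$object_id, obj$group, obj$period, st,
                obj$n_total, obj$overall_rel_surv)
}
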