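#' Stage weights for the screening index
#'
#' The screening index weights each stage's case proportion by the stage
#' number itself, so the default weight of stage code `c` is `c`. The
#' weighting is admittedly arbitrary — it gives the earliest detected
#' disease (stage 0) no weight and the "unknown" stage the largest — so
#' the map is fully configurable, including dropping the unknown stage.
#'
#' @param stages Integer vector of stage codes to weight (default 0–5,
#'   i.e. clinical stages 0–4 plus unknown = 5).
#' @param unknown_code Stage code of the "unknown" stage.
#' @param include_unknown Keep the unknown stage in the weighted sum
#'   (default `TRUE`, matching the conventional layout)?
#' @return A named numeric vector mapping stage code to weight.
#' @export
#' @examples
#' default_stage_weights()
#' default_stage_weights(include_unknown = FALSE)
default_stage_weights <- function(stages = 0:5, unknown_code = 5L,
                                  include_unknown = TRUE) {
  stages <- as.integer(stages)
  if (!include_unknown) stages <- setdiff(stages, as.integer(unknown_code))
  stats::setNames(as.numeric(stages), stages)
}

weights_for <- function(obj, weights) {
  codes <- as.character(obj$stages$stage)
  miss <- setdiff(codes, names(weights))
  if (length(miss)) {
    stop("no weight for stage code(s) ", paste(miss, collapse = ", "),
         " of object '", obj$object_id, "'", call. = FALSE)
  }
  w <- weights[codes]
  if (any(w < 0)) stop("stage weights must be non-negative", call. = FALSE)
  w
}

#' Stage-number-weighted mean of the case distribution
#'
#' The inner sum of the screening index: the relative proportion of cases
#' per stage, `n_i / N`, weighted by the stage weight (by default the
#' stage number), summed over all stage rows including the unknown stage.
#' Dimensionless; invariant to scaling all counts.
#'
#' @param obj A [health_object()].
#' @param weights Named numeric stage-weight map, see
#'   [default_stage_weights()]. When `NULL`, the stage codes themselves.
#' @return A single number.
#' @export
stage_weighted_mean <- function(obj, weights = NULL) {
  stopifnot(is_health_object(obj))
  if (is.null(weights)) weights <- default_stage_weights(obj$stages$stage)
  w <- weights_for(obj, weights)
  sum(obj$stages$n_stage / obj$n_total * w)
}

#' Survival-weighted case-mix mean
#'
#' The inner sum of the case-mix index: each stage's case count times its
#' stage-specific relative survival rate, summed and divided by the total
#' number of cases. On the survival (percent) scale. A populated stage
#' with a missing rate is an error.
#'
#' @param obj A [health_object()].
#' @return A single number on the percent survival scale.
#' @export
survival_weighted_case_mix <- function(obj) {
  stopifnot(is_health_object(obj))
  bad <- obj$stages$n_stage > 0 & !is.finite(obj$stages$rel_surv)
  if (any(bad)) {
    stop("populated stage(s) without a survival rate in object '",
         obj$object_id, "': stage ",
         paste(obj$stages$stage[bad], collapse = ", "), call. = FALSE)
  }
  s <- obj$stages
  sum(ifelse(s$n_stage > 0, s$n_stage * s$rel_surv, 0)) / obj$n_total
}

#' Extended standardized screening index (eSSI)
#'
#' Ratio of the stage-number-weighted case proportions of the benchmark
#' object over the reference object. Values above 1 mean cases are
#' detected and treated at later stages than in the reference; below 1,
#' earlier — the footprint of a more effective screening programme.
#'
#' @param obs Benchmark [health_object()].
#' @param ref Reference [health_object()].
#' @param weights Stage-weight map; `NULL` means stage codes as weights.
#' @return A positive ratio.
#' @export
essi <- function(obs, ref, weights = NULL) {
  if (is.null(weights)) {
    weights <- default_stage_weights(sort(unique(c(obs$stages$stage,
                                                   ref$stages$stage))))
  }
  denom <- stage_weighted_mean(ref, weights)
  if (denom <= 0) {
    stop("degenerate reference: stage-weighted mean is not positive",
         call. = FALSE)
  }
  stage_weighted_mean(obs, weights) / denom
}

#' Standardized case-mix index (SCI)
#'
#' Ratio of the survival-weighted case-mix means. Summarises how
#' favourable the stage mix is, weighting each stage by its own survival
#' rate; above 1 the benchmark's mix adapts faster to the background
#' population's survival than the reference's.
#'
#' @inheritParams essi
#' @return A positive ratio.
#' @export
sci <- function(obs, ref) {
  denom <- survival_weighted_case_mix(ref)
  if (denom <= 0) {
    stop("degenerate reference: case-mix mean is not positive", call. = FALSE)
  }
  survival_weighted_case_mix(obs) / denom
}

#' Standardized work-up index (SWI)
#'
#' Mean over shared stages of the benchmark/reference ratio of
#' stage-specific relative survival rates. The divisor is the number of
#' represented stages: only stages usable in both objects (rate present,
#' reference rate positive and — by default — cases present on both
#' sides) enter the average. Probes stage-wise survival and upstaging
#' quality.
#'
#' @inheritParams essi
#' @param require_cases Restrict the shared-stage set to stages with
#'   `n_stage > 0` in both objects (default `TRUE`).
#' @return A positive ratio.
#' @export
swi <- function(obs, ref, require_cases = TRUE) {
  m <- dplyr::inner_join(obs$stages, ref$stages, by = "stage",
                         suffix = c("_obs", "_ref"))
  ok <- is.finite(m$rel_surv_obs) & is.finite(m$rel_surv_ref) &
    m$rel_surv_ref > 0
  if (require_cases) ok <- ok & m$n_stage_obs > 0 & m$n_stage_ref > 0
  if (!any(ok)) {
    stop("no shared usable stages between '", obs$object_id, "' and '",
         ref$object_id, "'", call. = FALSE)
  }
  mean(m$rel_surv_obs[ok] / m$rel_surv_ref[ok])
}

#' Standardized treatment index (STI)
#'
#' Ratio of overall relative survival rates, divided by the case-mix
#' index as a risk adjustment: benchmark and reference can differ in
#' their stage distributions, and the SCI factors that difference out.
#' Probes treatment effectiveness net of case mix.
#'
#' @inheritParams essi
#' @return A positive ratio.
#' @export
sti <- function(obs, ref) {
  if (!is.finite(ref$overall_rel_surv) || ref$overall_rel_surv <= 0) {
    stop("degenerate reference: overall survival is not positive",
         call. = FALSE)
  }
  s <- sci(obs, ref)
  if (s <= 0) stop("case-mix index is not positive", call. = FALSE)
  (obs$overall_rel_surv / ref$overall_rel_surv) / s
}

#' Overall performance evaluation (OPE)
#'
#' The product SCI × SWI × STI. Note that the case-mix index appears in
#' STI's denominator, so it partially cancels inside OPE — the motivation
#' for the alternative composite [ropi()].
#'
#' @param sci_v,swi_v,sti_v Positive component index values.
#' @return A positive ratio.
#' @export
#' @examples
#' ope(0.993, 1.032, 1.023) # ~1.048
ope <- function(sci_v, swi_v, sti_v) {
  check_positive(sci_v = sci_v, swi_v = swi_v, sti_v = sti_v)
  sci_v * swi_v * sti_v
}

#' Relative overall performance index (ROPI)
#'
#' The composite (1 / eSSI) × SWI × STI. The screening index enters as a
#' reciprocal so that, like the other factors, larger is better; values
#' above 1 mean earlier treatment with higher relative survival than the
#' reference on average.
#'
#' @param essi_v,swi_v,sti_v Positive component index values.
#' @return A positive ratio.
#' @export
#' @examples
#' ropi(0.951, 1.032, 1.023) # ~1.110
ropi <- function(essi_v, swi_v, sti_v) {
  check_positive(essi_v = essi_v, swi_v = swi_v, sti_v = sti_v)
  (1 / essi_v) * swi_v * sti_v
}

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!all(is.finite(v)) || any(v <= 0)) {
      stop("'", nm, "' must be positive and finite", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Compute the full six-index panel for one benchmark object
#'
#' Assembles eSSI, SCI, SWI, STI and the composites OPE and ROPI for one
#' benchmark object against one reference object. The factorizations
#' OPE = SCI·SWI·STI and ROPI·eSSI = SWI·STI hold by construction.
#'
#' @inheritParams essi
#' @inheritParams swi
#' @return A one-row tibble with columns `object_id`, `group`, `period`,
#'   `essi`, `sci`, `swi`, `sti`, `ope`, `ropi`.
#' @export
#' @examples
#' path <- system.file("extdata", "seer17_reference_1999_2003.csv",
#'                     package = "survbench")
#' ref <- read_long_table(path)[[1]]
#' index_panel(ref, ref) # identity: all six are 1
index_panel <- function(obs, ref, weights = NULL, require_cases = TRUE) {
  stopifnot(is_health_object(obs), is_health_object(ref))
  e <- essi(obs, ref, weights)
  c_ <- sci(obs, ref)
  w <- swi(obs, ref, require_cases = require_cases)
  t_ <- sti(obs, ref)
  panel <- tibble::tibble(
    object_id = obs$object_id, group = obs$group, period = obs$period,
    essi = e, sci = c_, swi = w, sti = t_,
    ope = ope(c_, w, t_), ropi = ropi(e, w, t_)
  )
  if (!all(is.finite(unlist(panel[, 4:9]))) || any(unlist(panel[, 4:9]) <= 0)) {
    stop("index panel for '", obs$object_id,
         "' contains non-positive or non-finite values", call. = FALSE)
  }
  panel
}
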