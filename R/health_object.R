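#' Construct a health object
#'
#' A health object is one benchmark or reference unit (a country, state,
#' district or registry) observed in one period: its disease-stage case
#' distribution, the total case count, and stage-specific plus overall
#' relative survival rates.
#'
#' Relative survival rates may be supplied on the percent scale
#' (e.g. 89.1) or the fraction scale (e.g. 0.891). The scale is detected
#' per object — all rates at or below `scale_threshold` mean fraction, all
#' above mean percent — and rates are normalised to percent internally, so
#' downstream indices are identical for either input scale. Rates mixing
#' the two scales within one object are a validation error.
#'
#' @param object_id Unique identifier of the object within a run.
#' @param group Free-text label, e.g. a registry name.
#' @param period Opaque ordered period label, e.g. `"1999-2003"`. Period
#'   labels are never parsed as dates.
#' @param stages A data frame with columns `stage` (non-negative integer
#'   stage code), `n_stage` (case count) and `rel_surv` (relative survival
#'   rate). One code conventionally denotes the "unknown" stage; it is a
#'   stage row like any other. The total row is *not* part of `stages`.
#' @param n_total Total number of cases (must equal the sum of `n_stage`).
#' @param overall_rel_surv Overall relative survival on the same scale as
#'   the stage rates.
#' @param scale_threshold Boundary between the fraction and percent scales
#'   (default 1.2: relative survival can mildly exceed 100 percent, so a
#'   fraction can mildly exceed 1).
#' @param rel_surv_max Upper slack for percent-scale rates (default 120).
#'
#' @return An object of class `health_object`.
#' @seealso [validate_objects()], [read_long_table()]
#' @export
#' @examples
#' ref <- health_object(
#'   object_id = "R", group = "REF", period = "1999-2003",
#'   stages = data.frame(
#'     stage = 0:5,
#'     n_stage = c(167, 83081, 72195, 12617, 8449, 15262),
#'     rel_surv = c(93.6, 100, 90.2, 61.3, 22.5, 77.3)
#'   ),
#'   n_total = 191771, overall_rel_surv = 89.1
#' )
#' ref
health_object <- function(object_id, group, period, stages, n_total,
                          overall_rel_surv,
                          scale_threshold = 1.2, rel_surv_max = 120) {
  stopifnot(is.data.frame(stages),
            all(c("stage", "n_stage", "rel_surv") %in% names(stages)))
  stages <- tibble::as_tibble(stages)[, c("stage", "n_stage", "rel_surv")]
  stages$stage <- as.integer(stages$stage)
  stages <- dplyr::arrange(stages, .data$stage)

  rates <- c(stages$rel_surv, overall_rel_surv)
  rates <- rates[!is.na(rates)]
  scale <- if (length(rates) && all(rates <= scale_threshold)) "fraction" else "percent"
  if (scale == "fraction") {
    stages$rel_surv <- stages$rel_surv * 100
    overall_rel_surv <- overall_rel_surv * 100
  }

  structure(
    list(
      object_id = as.character(object_id),
      group = as.character(group),
      period = as.character(period),
      stages = stages,
      n_total = as.numeric(n_total),
      overall_rel_surv = as.numeric(overall_rel_surv)
    ),
    input_scale = scale,
    scale_threshold = scale_threshold,
    rel_surv_max = rel_surv_max,
    class = "health_object"
  )
}

#' @export
print.health_object <- function(x, ...) {
  cat(sprintf("<health_object> %s (%s), period %s\n",
              x$object_id, x$group, x$period))
  cat(sprintf("  n_total = %s, overall relative survival = %.4g%%\n",
              format(x$n_total, big.mark = ","), x$overall_rel_surv))
  print(x$stages, ...)
  invisible(x)
}

#' @export
format.health_object <- function(x, ...) {
  sprintf("health_object(%s, %s)", x$object_id, x$period)
}

is_health_object <- function(x) inherits(x, "health_object")

# Violations for a single object, as a tibble (zero rows when clean).
violations_one <- function(obj, scale_threshold = 1.2, rel_surv_max = 120) {
  bad <- list()
  note <- function(rule, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      object_id = obj$object_id, period = obj$period,
      rule = rule, detail = detail
    )
  }
  st <- obj$stages
  if (!is.finite(obj$n_total) || obj$n_total <= 0) {
    note("n_total_positive", sprintf("n_total = %s", format(obj$n_total)))
  }
  if (anyDuplicated(st$stage)) {
    dup <- unique(st$stage[duplicated(st$stage)])
    note("unique_stage_codes", paste("duplicated stage code(s):",
                                     paste(dup, collapse = ", ")))
  }
  if (any(st$n_stage < 0, na.rm = TRUE)) {
    note("n_stage_nonnegative", paste("negative count at stage",
      paste(st$stage[which(st$n_stage < 0)], collapse = ", ")))
  }
  s <- sum(st$n_stage)
  if (is.finite(obj$n_total) && obj$n_total > 0 && !isTRUE(all.equal(s, obj$n_total, tolerance = 0))) {
    note("stage_counts_sum_to_total",
         sprintf("sum of stage counts %s != n_total %s",
                 format(s), format(obj$n_total)))
  }
  # scale consistency is assessed on the rates as supplied; range on the
  # normalised percent scale
  pct <- c(st$rel_surv, obj$overall_rel_surv)
  pct <- pct[!is.na(pct)]
  raw <- if ((attr(obj, "input_scale") %||% "percent") == "fraction") pct / 100 else pct
  if (length(raw) && any(raw <= scale_threshold) && any(raw > scale_threshold)) {
    note("single_survival_scale",
         sprintf("rates on both sides of the scale threshold %.3g", scale_threshold))
  }
  if (any(pct < 0) || any(pct > rel_surv_max)) {
    note("rel_surv_range", sprintf("rate(s) outside [0, %g] percent", rel_surv_max))
  }
  if (length(bad)) dplyr::bind_rows(bad) else empty_violations()
}

empty_violations <- function() {
  tibble::tibble(object_id = character(), period = character(),
                 rule = character(), detail = character())
}

#' Validate a list of health objects
#'
#' Checks every invariant of the container — positive total, stage counts
#' summing exactly to the total, unique stage codes, a single survival
#' scale per object, rates within range — and reports violations instead
#' of raising, so a multi-registry run can drop offenders and continue.
#'
#' @param objects A list of [health_object()]s (a single object is
#'   accepted and wrapped).
#' @param scale_threshold,rel_surv_max See [health_object()].
#' @return A tibble with columns `object_id`, `period`, `rule`, `detail`;
#'   zero rows iff everything is valid.
#' @export
validate_objects <- function(objects, scale_threshold = 1.2, rel_surv_max = 120) {
  if (is_health_object(objects)) objects <- list(objects)
  stopifnot(all(vapply(objects, is_health_object, logical(1))))
  if (!length(objects)) return(empty_violations())
  dplyr::bind_rows(lapply(objects, violations_one,
                          scale_threshold = scale_threshold,
                          rel_surv_max = rel_surv_max))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
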