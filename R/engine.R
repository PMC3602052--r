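#' Configuration of a benchmark run
#'
#' @param mode `"cross_sectional"` (all objects share the reference's
#'   period) or `"longitudinal"` (objects may span periods while the
#'   reference stays fixed in time).
#' @param reference_id Object id of the reference ("best performer").
#' @param reference_period Period label of the reference.
#' @param weights Stage-weight map for the screening index; `NULL` uses
#'   the stage codes themselves.
#' @param include_reference Include the reference itself as a benchmark
#'   row (default `TRUE`; its six indices are then exactly 1)?
#' @param sort_key Index the cross-sectional table is sorted by,
#'   descending (default `"ropi"`; `NULL` keeps input order).
#' @param strict Abort on any invalid or out-of-period object instead of
#'   dropping it with a warning.
#' @param require_cases Passed to [swi()].
#' @param period_order Optional explicit ordering of period labels for
#'   longitudinal runs; default is order of first appearance. Labels are
#'   opaque, never parsed as dates.
#' @param neutral_band Half-width of the band around 1 inside which
#'   [interpret_panel()] calls an index comparable to the reference.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("cross_sectional", "longitudinal"),
                       reference_id, reference_period,
                       weights = NULL, include_reference = TRUE,
                       sort_key = "ropi", strict = FALSE,
                       require_cases = TRUE, period_order = NULL,
                       neutral_band = 0.005) {
  mode <- match.arg(mode)
  if (!is.null(sort_key)) {
    sort_key <- match.arg(sort_key,
                          c("ropi", "ope", "essi", "sci", "swi", "sti"))
  }
  structure(list(mode = mode,
                 reference_id = as.character(reference_id),
                 reference_period = as.character(reference_period),
                 weights = weights,
                 include_reference = isTRUE(include_reference),
                 sort_key = sort_key, strict = isTRUE(strict),
                 require_cases = isTRUE(require_cases),
                 period_order = period_order,
                 neutral_band = neutral_band),
            class = "run_config")
}

new_benchmark_table <- function(rows, mode, reference_id, reference_period) {
  structure(rows, mode = mode, reference_id = reference_id,
            reference_period = reference_period,
            class = c("benchmark_table", class(rows)))
}

#' @export
print.benchmark_table <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

find_reference <- function(objects, cfg) {
  hit <- vapply(objects, function(o)
    o$object_id == cfg$reference_id && o$period == cfg$reference_period,
    logical(1))
  if (sum(hit) != 1L) {
    stop("reference (", cfg$reference_id, ", ", cfg$reference_period,
         ") matches ", sum(hit), " loaded objects; need exactly 1",
         call. = FALSE)
  }
  objects[[which(hit)]]
}

drop_invalid <- function(objects, cfg) {
  report <- validate_objects(objects)
  if (!nrow(report)) return(objects)
  msg <- paste(sprintf("  [%s | %s] %s: %s", report$object_id,
                       report$period, report$rule, report$detail),
               collapse = "\n")
  if (cfg$strict) stop("invalid objects in strict mode:\n", msg, call. = FALSE)
  bad <- unique(paste(report$object_id, report$period, sep = "\r"))
  keep <- !vapply(objects, function(o)
    paste(o$object_id, o$period, sep = "\r") %in% bad, logical(1))
  warning("dropping ", sum(!keep), " invalid object(s):\n", msg,
          call. = FALSE)
  objects[keep]
}

#' Cross-sectional benchmark run
#'
#' Scores every object of the reference's period against the reference;
#' all benchmark objects must belong to the same time interval as the
#' reference. The reference itself is included as a benchmark row by
#' default, yielding the all-ones anchor row. Rows are sorted by
#' `cfg$sort_key` descending.
#'
#' @param objects List of [health_object()]s.
#' @param cfg A [run_config()] with `mode = "cross_sectional"`.
#' @return A `benchmark_table`: a tibble of six-index rows with the run
#'   mode and reference recorded as attributes.
#' @export
cross_sectional <- function(objects, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  objects <- drop_invalid(objects, cfg)
  ref <- find_reference(objects, cfg)
  off <- vapply(objects, function(o) o$period != cfg$reference_period,
                logical(1))
  if (any(off)) {
    what <- vapply(objects[off], function(o)
      sprintf("(%s, %s)", o$object_id, o$period), character(1))
    msg <- paste("objects outside the reference period:",
                 paste(what, collapse = ", "))
    if (cfg$strict) stop(msg, call. = FALSE)
    warning("dropping ", msg, call. = FALSE)
    objects <- objects[!off]
  }
  if (!cfg$include_reference) {
    objects <- Filter(function(o) o$object_id != cfg$reference_id, objects)
  }
  rows <- dplyr::bind_rows(lapply(objects, index_panel, ref = ref,
                                  weights = cfg$weights,
                                  require_cases = cfg$require_cases))
  if (!is.null(cfg$sort_key)) {
    rows <- dplyr::arrange(rows, dplyr::desc(.data[[cfg$sort_key]]),
                           .data$object_id)
  }
  new_benchmark_table(rows, "cross_sectional",
                      cfg$reference_id, cfg$reference_period)
}

#' Longitudinal benchmark run
#'
#' Scores every (object, period) pair against a single reference fixed in
#' time, so each object traces a trajectory of index values across
#' periods. The reference's own (id, period) row equals one in all six
#' indices. Rows are ordered by group, then period (appearance order or
#' `cfg$period_order`), then object id.
#'
#' @inheritParams cross_sectional
#' @return A `benchmark_table`.
#' @export
longitudinal <- function(objects, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  objects <- drop_invalid(objects, cfg)
  ref <- find_reference(objects, cfg)
  rows <- dplyr::bind_rows(lapply(objects, index_panel, ref = ref,
                                  weights = cfg$weights,
                                  require_cases = cfg$require_cases))
  periods <- cfg$period_order %||% unique(rows$period)
  rows$period <- factor(rows$period, levels = periods)
  rows <- dplyr::arrange(rows, .data$group, .data$period, .data$object_id)
  rows$period <- as.character(rows$period)
  new_benchmark_table(rows, "longitudinal",
                      cfg$reference_id, cfg$reference_period)
}

#' Run a benchmark according to a configuration
#'
#' Dispatches to [cross_sectional()] or [longitudinal()] based on
#' `cfg$mode`.
#'
#' @inheritParams cross_sectional
#' @return A `benchmark_table`.
#' @export
run_benchmark <- function(objects, cfg) {
  switch(cfg$mode,
         cross_sectional = cross_sectional(objects, cfg),
         longitudinal = longitudinal(objects, cfg))
}

#' Plain-language interpretation of an index panel
#'
#' Translates each of the six indices into the standard reading: an index
#' above or below one flags a quality advance or gap relative to the
#' reference. eSSI > 1 means cases are treated at a later time point;
#' SCI < 1, survival conditions adapting more slowly to the background
#' population's; SWI < 1, lower average stage-wise survival; STI < 1,
#' lower stage-adjusted overall survival; OPE/ROPI > 1, earlier treatment
#' with higher relative survival on average. Values within
#' `neutral_band` of 1 are reported as comparable to the reference.
#'
#' @param panel A one-row index panel (from [index_panel()] or one row of
#'   a `benchmark_table`).
#' @param neutral_band Half-width of the "comparable" band (default
#'   0.005, i.e. indistinguishable at three printed decimals).
#' @return A character vector with one statement per index.
#' @export
interpret_panel <- function(panel, neutral_band = 0.005) {
  stopifnot(nrow(panel) == 1)
  phr <- list(
    essi = c("cases are treated at a later time point than in the reference",
             "cases are treated at an earlier time point than in the reference"),
    sci = c("survival conditions adapt to the background population's faster than in the reference",
            "survival conditions adapt to the background population's more slowly than in the reference"),
    swi = c("average stage-wise relative survival is higher than in the reference",
            "average stage-wise relative survival is lower than in the reference"),
    sti = c("stage-adjusted overall relative survival is higher than in the reference",
            "stage-adjusted overall relative survival is lower than in the reference"),
    ope = c("on average, earlier treatment with higher relative survival than the reference",
            "on average, later treatment with lower relative survival than the reference"),
    ropi = c("on average, earlier treatment with higher relative survival than the reference",
             "on average, later treatment with lower relative survival than the reference")
  )
  lab <- c(essi = "eSSI", sci = "SCI", swi = "SWI", sti = "STI",
           ope = "OPE", ropi = "ROPI")
  vapply(names(phr), function(ix) {
    v <- panel[[ix]]
    if (abs(v - 1) <= neutral_band) {
      sprintf("%s = %.3f: comparable to the reference", lab[[ix]], v)
    } else {
      sprintf("%s = %.3f: %s", lab[[ix]], v, phr[[ix]][if (v > 1) 1 else 2])
    }
  }, character(1), USE.NAMES = FALSE)
}
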