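#' Default column schema for long-format registry tables
#'
#' The long format has one row per (object, period, stage): a group label,
#' a period label, an object identifier, a stage code, the case count at
#' that stage, the total case count, and the stage-specific relative
#' survival rate. One designated stage code is the "total" row carrying
#' the object's total N and overall relative survival; one is the
#' "unknown" stage. Override names or codes to adapt other registries'
#' nomenclatures.
#'
#' @param group,period,object_id,stage,n_stage,n_total,rel_surv Column
#'   names in the CSV.
#' @param total_code Stage code of the total/overall row (default 6).
#' @param unknown_code Stage code of the "unknown" stage (default 5).
#' @return A named list used as the `schema` argument of
#'   [read_long_table()].
#' @export
long_table_schema <- function(group = "group", period = "period",
                              object_id = "object_id", stage = "stage",
                              n_stage = "n_stage", n_total = "n_total",
                              rel_surv = "rel_surv",
                              total_code = 6L, unknown_code = 5L) {
  list(group = group, period = period, object_id = object_id,
       stage = stage, n_stage = n_stage, n_total = n_total,
       rel_surv = rel_surv,
       total_code = as.integer(total_code),
       unknown_code = as.integer(unknown_code))
}

#' Read a long-format registry summary table
#'
#' Reads a CSV with one row per (object, period, stage) and assembles one
#' [health_object()] per distinct (object_id, period). The designated
#' total row is consumed into `n_total` and `overall_rel_surv` and is not
#' kept as a stage record. All container invariants are validated;
#' violations are reported with the offending object and rule.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column-name/stage-code mapping, see [long_table_schema()].
#' @param strict If `TRUE` (default) any validation violation is an
#'   error; if `FALSE`, offending objects are dropped with a warning.
#' @param keep_invalid Return objects regardless of validation violations
#'   (structural defects still error). For callers that want to inspect
#'   violations themselves via [validate_objects()].
#' @param scale_threshold,rel_surv_max See [health_object()].
#' @return A list of `health_object`s (empty, with a warning, for a
#'   header-only file).
#' @export
#' @examples
#' path <- system.file("extdata", "seer17_reference_1999_2003.csv",
#'                     package = "survbench")
#' objs <- read_long_table(path)
#' objs[[1]]
read_long_table <- function(path, schema = long_table_schema(),
                            strict = TRUE, keep_invalid = FALSE,
                            scale_threshold = 1.2, rel_surv_max = 120) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- unlist(schema[c("group", "period", "object_id", "stage",
                         "n_stage", "n_total", "rel_surv")])
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(
    group = as.character(raw[[schema$group]]),
    period = as.character(raw[[schema$period]]),
    object_id = as.character(raw[[schema$object_id]]),
    stage = as.integer(raw[[schema$stage]]),
    n_stage = as.numeric(raw[[schema$n_stage]]),
    n_total = as.numeric(raw[[schema$n_total]]),
    rel_surv = as.numeric(raw[[schema$rel_surv]]),
    .row = seq_len(nrow(raw))
  )
  if (!nrow(df)) {
    warning("'", path, "' has a header but no data rows", call. = FALSE)
    return(list())
  }

  dup <- duplicated(df[, c("object_id", "period", "stage")])
  if (any(dup)) {
    stop("duplicate (object_id, period, stage) at row(s): ",
         paste(df$.row[dup], collapse = ", "), call. = FALSE)
  }

  keys <- unique(df[, c("object_id", "period")])
  objects <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sub <- df[df$object_id == keys$object_id[k] & df$period == keys$period[k], ]
    tot <- sub[sub$stage == schema$total_code, ]
    if (nrow(tot) != 1L) {
      stop(sprintf(
        "object '%s' period '%s': expected exactly one total row (stage code %d), found %d (rows %s)",
        keys$object_id[k], keys$period[k], schema$total_code, nrow(tot),
        paste(sub$.row, collapse = ", ")), call. = FALSE)
    }
    st <- sub[sub$stage != schema$total_code, ]
    objects[[k]] <- health_object(
      object_id = keys$object_id[k],
      group = sub$group[1],
      period = keys$period[k],
      stages = st[, c("stage", "n_stage", "rel_surv")],
      n_total = tot$n_total[1],
      overall_rel_surv = tot$rel_surv[1],
      scale_threshold = scale_threshold,
      rel_surv_max = rel_surv_max
    )
  }

  if (keep_invalid) return(objects)
  report <- validate_objects(objects, scale_threshold = scale_threshold,
                             rel_surv_max = rel_surv_max)
  if (nrow(report)) {
    msg <- paste(sprintf("  [%s | %s] %s: %s", report$object_id,
                         report$period, report$rule, report$detail),
                 collapse = "\n")
    if (strict) {
      stop("validation failed for '", path, "':\n", msg, call. = FALSE)
    }
    bad <- unique(paste(report$object_id, report$period, sep = "\r"))
    keep <- !vapply(objects, function(o)
      paste(o$object_id, o$period, sep = "\r") %in% bad, logical(1))
    warning("dropping ", sum(!keep), " invalid object(s):\n", msg, call. = FALSE)
    objects <- objects[keep]
  }
  objects
}

#' Write health objects back to the long format
#'
#' Emits the same CSV layout [read_long_table()] reads (percent survival
#' scale), appending the total row per object. `read_long_table()` on the
#' result reproduces the objects field-for-field.
#'
#' @param objects List of [health_object()]s.
#' @param path Output CSV path.
#' @param schema See [long_table_schema()].
#' @return `path`, invisibly.
#' @export
write_long_table <- function(objects, path, schema = long_table_schema()) {
  if (is_health_object(objects)) objects <- list(objects)
  rows <- lapply(objects, function(o) {
    tibble::tibble(
      group = o$group, period = o$period, object_id = o$object_id,
      stage = c(o$stages$stage, schema$total_code),
      n_stage = c(o$stages$n_stage, o$n_total),
      n_total = o$n_total,
      rel_surv = c(o$stages$rel_surv, o$overall_rel_surv)
    )
  })
  out <- dplyr::bind_rows(rows)
  names(out) <- unlist(schema[c("group", "period", "object_id", "stage",
                                "n_stage", "n_total", "rel_surv")])
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a benchmark result table and its human-readable report
#'
#' The CSV keeps full floating-point precision so results round-trip
#' exactly; the companion plain-text report rounds each index to three
#' decimals, matching how such panels are conventionally presented.
#'
#' @param table A `benchmark_table` from [cross_sectional()] or
#'   [longitudinal()].
#' @param path Output CSV path.
#' @param report_path Optional path for the rounded text report; default
#'   replaces the CSV extension with `.txt`. `NULL` suppresses it.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path,
                          report_path = sub("\\.csv$", ".txt", path)) {
  stopifnot(inherits(table, "benchmark_table"), nrow(table) > 0)
  # %.17g is the shortest representation guaranteed to round-trip a double
  full <- function(x) sprintf("%.17g", x)
  out <- tibble::tibble(
    mode = attr(table, "mode"),
    reference_id = attr(table, "reference_id"),
    reference_period = attr(table, "reference_period"),
    group = table$group, period = table$period, object_id = table$object_id,
    eSSI = full(table$essi), SCI = full(table$sci), SWI = full(table$swi),
    STI = full(table$sti), OPE = full(table$ope), ROPI = full(table$ropi)
  )
  readr::write_csv(out, path)
  if (!is.null(report_path) && !identical(report_path, path)) {
    writeLines(format_report(table), report_path)
  }
  invisible(path)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path Path to the results CSV.
#' @return A `benchmark_table`.
#' @export
read_results <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("mode", "reference_id", "reference_period", "group", "period",
            "object_id", "eSSI", "SCI", "SWI", "STI", "OPE", "ROPI")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("not a results table, missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- tibble::tibble(
    object_id = as.character(df$object_id), group = as.character(df$group),
    period = as.character(df$period),
    essi = df$eSSI, sci = df$SCI, swi = df$SWI, sti = df$STI,
    ope = df$OPE, ropi = df$ROPI
  )
  new_benchmark_table(rows, mode = df$mode[1],
                      reference_id = as.character(df$reference_id[1]),
                      reference_period = as.character(df$reference_period[1]))
}

# Fixed-width rounded view of a benchmark table (three decimals, the
# conventional presentation for index panels).
format_report <- function(table) {
  hdr <- sprintf("Benchmark run (%s), reference: %s @ %s",
                 attr(table, "mode"), attr(table, "reference_id"),
                 attr(table, "reference_period"))
  df <- as.data.frame(table)
  num <- c("essi", "sci", "swi", "sti", "ope", "ropi")
  for (v in num) df[[v]] <- sprintf("%.3f", df[[v]])
  names(df) <- c("object_id", "group", "period",
                 "eSSI", "SCI", "SWI", "STI", "OPE", "ROPI")
  body <- utils::capture.output(print(df, row.names = FALSE))
  c(hdr, strrep("-", nchar(hdr)), body)
}
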