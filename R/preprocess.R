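# Quality filtering and fold-change computation for probe measurements.
#
# Three filters, applied in this order:
#   1. low signal      — either channel strictly below the array's threshold
#   2. relative error  — summed error large relative to the signal change
#   3. total error     — per-probe error summed over treatment arrays exceeds
#                        the same sum over control arrays (needs replicates)
# After filtering, %CFC and log2 fold change are computed per retained probe.

#' Percent change from control
#'
#' `100 * (treated - control) / control`, signed. The control signal must be
#' positive; probes with zero control signal are expected to have been removed
#' by the low-signal filter beforehand.
#'
#' @param treated_signal,control_signal Fluorescence signals (vectorised).
#' @return Signed percent change from control.
#' @examples
#' compute_cfc(1500, 1000) # +50
#' compute_cfc(800, 1000)  # -20
#' @export
compute_cfc <- function(treated_signal, control_signal) {
  if (any(control_signal <= 0)) {
    stop("undefined CFC: control signal must be > 0 ",
         "(apply the low-signal filter first)", call. = FALSE)
  }
  100 * (treated_signal - control_signal) / control_signal
}

#' Log2 fold change
#'
#' @param treated_signal,control_signal Positive fluorescence signals.
#' @return `log2(treated / control)`.
#' @export
compute_log2fc <- function(treated_signal, control_signal) {
  if (any(treated_signal <= 0) || any(control_signal <= 0)) {
    stop("undefined log2 fold change: signals must be > 0", call. = FALSE)
  }
  log2(treated_signal / control_signal)
}

#' Low-signal filter
#'
#' Removes a probe iff `min(treated_signal, control_signal)` is strictly
#' below the array design's low-signal threshold (1,000 units for KAM-1325,
#' 500 for KAM-2000). Equality retains. Using the minimum of the two channels
#' means either channel being low disqualifies the probe, which also protects
#' the %CFC denominator.
#'
#' @param measurements A `probe_table`.
#' @param spec An [array_spec()].
#' @return List with `kept` (a `probe_table`, input order preserved) and
#'   `removed` (character vector of probe ids).
#' @export
filter_low_signal <- function(measurements, spec) {
  lo <- pmin(measurements$treated_signal, measurements$control_signal) <
    spec$low_signal_threshold
  list(kept = measurements[!lo, , drop = FALSE],
       removed = measurements$probe_id[lo])
}

#' Relative-error filter
#'
#' Removes a probe iff
#' `(treated_error + control_error) / |treated_signal - control_signal|`
#' exceeds `ratio_threshold`. A zero signal change with nonzero summed error
#' counts as an infinite ratio and is removed; zero change with zero error is
#' retained. The default threshold 1 removes probes whose signal change lies
#' within the summed reported error.
#'
#' @param measurements A `probe_table`.
#' @param ratio_threshold Positive ratio, default 1.
#' @return List with `kept` and `removed` as in [filter_low_signal()].
#' @export
filter_relative_error <- function(measurements, ratio_threshold = 1.0) {
  stopifnot(ratio_threshold > 0)
  err <- measurements$treated_error + measurements$control_error
  delta <- abs(measurements$treated_signal - measurements$control_signal)
  ratio <- ifelse(delta == 0, ifelse(err > 0, Inf, 0), err / delta)
  bad <- ratio > ratio_threshold
  list(kept = measurements[!bad, , drop = FALSE],
       removed = measurements$probe_id[bad])
}

#' Total-error filter across replicate arrays
#'
#' Blacklists a probe iff the sum of its reported errors (treated + control
#' channel) over all treatment tables strictly exceeds the same sum over all
#' control tables. With a single paired table per condition — the common
#' single-screen case — the treated channel's errors play the role of the
#' treatment arrays and the control channel's errors that of the control
#' arrays.
#'
#' @param treatment_tables List of `probe_table`s for the treated condition
#'   (their `treated_*` columns are used).
#' @param control_tables List of `probe_table`s for the control condition
#'   (their `control_*` columns are used). Defaults to `treatment_tables`,
#'   i.e. the paired-channel reading.
#' @return Character vector of blacklisted probe ids.
#' @export
filter_total_error <- function(treatment_tables, control_tables = treatment_tables) {
  if (!is.data.frame(treatment_tables[[1]])) {
    stop("treatment_tables must be a list of probe tables", call. = FALSE)
  }
  sum_errors <- function(tables, col) {
    ids <- sort(unique(unlist(lapply(tables, `[[`, "probe_id"))), method = "radix")
    total <- stats::setNames(numeric(length(ids)), ids)
    seen <- stats::setNames(logical(length(ids)), ids)
    for (tb in tables) {
      total[tb$probe_id] <- total[tb$probe_id] + tb[[col]]
      seen[tb$probe_id] <- TRUE
    }
    if (!all(seen)) stop("probe missing from a table", call. = FALSE)
    total
  }
  treat <- sum_errors(treatment_tables, "treated_error")
  ctrl <- sum_errors(control_tables, "control_error")
  shared <- intersect(names(treat), names(ctrl))
  if (length(shared) != length(treat) || length(shared) != length(ctrl)) {
    only <- c(setdiff(names(treat), names(ctrl)),
              setdiff(names(ctrl), names(treat)))
    stop("validation error: probe(s) present in one condition only: ",
         paste(utils::head(only, 5), collapse = ", "), call. = FALSE)
  }
  names(treat)[treat[shared] > ctrl[shared]]
}

#' Run the full preprocessing pipeline
#'
#' Applies the three filters in order (low-signal, relative-error,
#' total-error), then computes `cfc_percent` and `log2fc` for every retained
#' probe. The pipeline is idempotent: applying it to its own output removes
#' nothing further.
#'
#' @param measurements A `probe_table` (single treated-vs-control screen), or
#'   a list of them when replicate arrays are available.
#' @param spec An [array_spec()].
#' @param config List of options: `relative_error_threshold` (default 1),
#'   `apply_low_signal`, `apply_relative_error`, `apply_total_error`
#'   (logical toggles, all default `TRUE`).
#' @return List with `measurements` (retained `probe_table` annotated with
#'   `cfc_percent` and `log2fc`) and `report` (a `filter_report`).
#' @export
preprocess_pipeline <- function(measurements, spec, config = list()) {
  cfg <- utils::modifyList(list(relative_error_threshold = 1.0,
                                apply_low_signal = TRUE,
                                apply_relative_error = TRUE,
                                apply_total_error = TRUE), config)
  tables <- if (is.data.frame(measurements)) list(measurements) else measurements
  current <- tables[[1]]
  if (length(tables) > 1) {
    # replicate tables share the probe panel; filter on the first (reference)
    # table's signals, total error uses all of them
    ids <- current$probe_id
    for (tb in tables[-1]) {
      if (!setequal(tb$probe_id, ids)) {
        stop("validation error: replicate tables must share probe ids",
             call. = FALSE)
      }
    }
  }
  n_input <- nrow(current)
  removed_low <- character()
  removed_rel <- character()
  removed_tot <- character()

  if (isTRUE(cfg$apply_low_signal)) {
    r <- filter_low_signal(current, spec)
    current <- r$kept
    removed_low <- r$removed
  }
  if (isTRUE(cfg$apply_relative_error)) {
    r <- filter_relative_error(current, cfg$relative_error_threshold)
    current <- r$kept
    removed_rel <- r$removed
  }
  # The total-error comparison targets antibodies with reproducibly inflated
  # error on the treated arrays; with a single array pair the per-probe error
  # difference is a single noisy draw and the strict comparison would remove
  # about half the panel at random, so the rule is applied only when
  # replicate tables are available.
  if (isTRUE(cfg$apply_total_error) && length(tables) >= 2) {
    blacklist <- filter_total_error(tables)
    keep <- !current$probe_id %in% blacklist
    removed_tot <- current$probe_id[!keep]
    current <- current[keep, , drop = FALSE]
  }

  current$cfc_percent <- compute_cfc(current$treated_signal,
                                     current$control_signal)
  current$log2fc <- compute_log2fc(pmax(current$treated_signal,
                                        .Machine$double.xmin),
                                   current$control_signal)
  rownames(current) <- NULL

  report <- structure(list(
    n_input = n_input,
    n_low_signal_removed = length(removed_low),
    n_relative_error_removed = length(removed_rel),
    n_total_error_removed = length(removed_tot),
    n_retained = nrow(current),
    removed_probe_ids = list(low_signal = removed_low,
                             relative_error = removed_rel,
                             total_error = removed_tot)
  ), class = "filter_report")
  stopifnot(report$n_input == report$n_retained +
              report$n_low_signal_removed +
              report$n_relative_error_removed +
              report$n_total_error_removed)
  list(measurements = current, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  input probes:            %d\n", x$n_input))
  cat(sprintf("  removed (low signal):    %d\n", x$n_low_signal_removed))
  cat(sprintf("  removed (relative err):  %d\n", x$n_relative_error_removed))
  cat(sprintf("  removed (total err):     %d\n", x$n_total_error_removed))
  cat(sprintf("  retained:                %d\n", x$n_retained))
  invisible(x)
}

#' Serialize a filter report
#'
#' Writes the report as JSON (machine-readable) or plain text.
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @param format `"json"` or `"text"`.
#' @export
write_filter_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  invisible(NULL)
}
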