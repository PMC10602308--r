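# Reading and writing of probe tables, kinase-substrate relation tables and
# lead tables. All formats are delimited text with a required header; tab is
# the default separator (phosphosite labels and gene symbols never contain
# tabs), comma is accepted via `sep`.

PROBE_COLUMNS <- c("probe_id", "target", "site",
                   "treated_signal", "treated_error",
                   "control_signal", "control_error")

RELATION_COLUMNS <- c("kinase", "substrate", "site", "effect")

EFFECT_LEVELS <- c("activation", "inhibition", "unknown")

#' Array design specification
#'
#' Describes an antibody microarray design: its identifier, the fluorescence
#' level below which a signal is considered "low" and removed, and the nominal
#' number of probes. Two designs are bundled: `"KAM-1325"` (1,325 probes,
#' low-signal threshold 1,000 units) and `"KAM-2000"` (2,000 probes,
#' threshold 500 units).
#'
#' @param array_id Character identifier of the design. If it matches a bundled
#'   design and the other arguments are missing, the bundled values are used.
#' @param low_signal_threshold Fluorescence units; signals strictly below this
#'   are treated as low. Must be > 0.
#' @param n_probes_nominal Nominal probe count of the design.
#' @return An object of class `array_spec`.
#' @examples
#' array_spec("KAM-1325")
#' array_spec("custom", low_signal_threshold = 750, n_probes_nominal = 900)
#' @export
array_spec <- function(array_id, low_signal_threshold = NULL,
                       n_probes_nominal = NULL) {
  bundled <- list(
    "KAM-1325" = list(threshold = 1000, n = 1325L),
    "KAM-2000" = list(threshold = 500,  n = 2000L)
  )
  if (is.null(low_signal_threshold) || is.null(n_probes_nominal)) {
    if (!array_id %in% names(bundled)) {
      stop("unknown array design '", array_id,
           "'; supply low_signal_threshold and n_probes_nominal explicitly",
           call. = FALSE)
    }
    b <- bundled[[array_id]]
    if (is.null(low_signal_threshold)) low_signal_threshold <- b$threshold
    if (is.null(n_probes_nominal)) n_probes_nominal <- b$n
  }
  stopifnot(is.numeric(low_signal_threshold), low_signal_threshold > 0,
            is.numeric(n_probes_nominal), n_probes_nominal >= 1)
  structure(
    list(array_id = as.character(array_id),
         low_signal_threshold = as.numeric(low_signal_threshold),
         n_probes_nominal = as.integer(n_probes_nominal)),
    class = "array_spec"
  )
}

#' @export
print.array_spec <- function(x, ...) {
  cat(sprintf("<array_spec> %s: %d probes nominal, low-signal threshold %g units\n",
              x$array_id, x$n_probes_nominal, x$low_signal_threshold))
  invisible(x)
}

# Phosphosite grammar: one residue letter in {S,T,Y} followed by an integer
# position >= 1, or the sentinel "pan" for pan-specific (expression) probes.
site_is_valid <- function(site) {
  site == "pan" | grepl("^[STY][1-9][0-9]*$", site)
}

format_error <- function(...) stop(..., call. = FALSE)

apply_aliases <- function(symbols, aliases) {
  if (is.null(aliases)) return(symbols)
  if (!all(c("alias", "symbol") %in% names(aliases))) {
    format_error("alias table must have columns 'alias' and 'symbol'")
  }
  idx <- match(toupper(symbols), toupper(aliases$alias))
  out <- symbols
  out[!is.na(idx)] <- toupper(aliases$symbol[idx[!is.na(idx)]])
  out
}

read_delim_table <- function(path, sep) {
  if (!file.exists(path)) format_error("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = NA, check.names = TRUE)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    format_error("format error in '", path, "': missing column(s) ",
                 paste(missing, collapse = ", "))
  }
}

#' Read a probe measurement table
#'
#' One row per antibody probe with paired treated/control signals and errors.
#' Required columns: `probe_id`, `target`, `site`, `treated_signal`,
#' `treated_error`, `control_signal`, `control_error`. Row order is
#' preserved; gene symbols are upper-cased; optional aliases are resolved.
#' Derived quantities (`cfc_percent`, `log2fc`) are *not* computed here, see
#' [preprocess_pipeline()].
#'
#' @param path Path to a delimited text file.
#' @param spec An [array_spec()]; recorded as an attribute of the result.
#' @param sep Field separator, default tab.
#' @param aliases Optional data frame with columns `alias`, `symbol` mapping
#'   alternative gene names (e.g. BCL2 for BAD, p70S6K for RPS6KB1) onto the
#'   symbols used in the relation table.
#' @return A `data.frame` of class `probe_table`.
#' @export
read_probe_table <- function(path, spec = NULL, sep = "\t", aliases = NULL) {
  df <- read_delim_table(path, sep)
  check_columns(df, PROBE_COLUMNS, path)
  df <- df[PROBE_COLUMNS]
  as_probe_table(df, spec = spec, aliases = aliases, origin = path)
}

#' Validate a probe measurement data frame
#'
#' @param df Data frame with the probe-table columns.
#' @inheritParams read_probe_table
#' @param origin Label used in error messages.
#' @return A validated `probe_table`.
#' @export
as_probe_table <- function(df, spec = NULL, aliases = NULL, origin = "probe table") {
  df$probe_id <- as.character(df$probe_id)
  df$target <- toupper(as.character(df$target))
  df$target <- apply_aliases(df$target, aliases)
  df$site <- as.character(df$site)
  for (col in c("treated_signal", "treated_error",
                "control_signal", "control_error")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      format_error("validation error in ", origin, ": non-numeric ", col,
                   " at row ", bad[1])
    }
    neg <- which(v < 0)
    if (length(neg) > 0) {
      format_error("validation error in ", origin, ": negative ", col,
                   " at row ", neg[1])
    }
    df[[col]] <- v
  }
  dup <- which(duplicated(df$probe_id))
  if (length(dup) > 0) {
    format_error("validation error in ", origin, ": duplicate probe_id '",
                 df$probe_id[dup[1]], "' at row ", dup[1])
  }
  empty <- which(!nzchar(df$target))
  if (length(empty) > 0) {
    format_error("validation error in ", origin, ": empty target at row ",
                 empty[1])
  }
  badsite <- which(!site_is_valid(df$site))
  if (length(badsite) > 0) {
    format_error("validation error in ", origin, ": invalid site '",
                 df$site[badsite[1]], "' at row ", badsite[1],
                 " (expected one of S/T/Y + position, or 'pan')")
  }
  rownames(df) <- NULL
  structure(df, class = c("probe_table", "data.frame"),
            array_id = if (!is.null(spec)) spec$array_id else NA_character_)
}

#' Write a probe table
#'
#' @param x A `probe_table` (or compatible data frame).
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_probe_table <- function(x, path, sep = "\t") {
  cols <- intersect(c(PROBE_COLUMNS, "cfc_percent", "log2fc"), names(x))
  utils::write.table(as.data.frame(x)[cols], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a kinase-substrate relation table
#'
#' Accepts either the four-column layout `kinase, substrate, site, effect`
#' or a SIF-like three-column layout `kinase, effect, substrate@site`.
#' Effects must be one of `activation`, `inhibition`, `unknown`. Duplicate
#' `(kinase, substrate, site)` triples are rejected.
#'
#' @inheritParams read_probe_table
#' @return A `data.frame` of class `ks_relations` with columns
#'   `kinase`, `substrate`, `site`, `effect`.
#' @export
read_ks_relations <- function(path, sep = "\t", aliases = NULL) {
  df <- read_delim_table(path, sep)
  if (all(RELATION_COLUMNS %in% names(df))) {
    df <- df[RELATION_COLUMNS]
  } else if (ncol(df) == 3) {
    # SIF-like: kinase, effect, substrate@site
    tgt <- as.character(df[[3]])
    parts <- strsplit(tgt, "@", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 2L)
    if (length(bad) > 0) {
      format_error("format error in '", path, "': expected 'substrate@site' at row ",
                   bad[1])
    }
    df <- data.frame(kinase = as.character(df[[1]]),
                     substrate = vapply(parts, `[`, "", 1L),
                     site = vapply(parts, `[`, "", 2L),
                     effect = as.character(df[[2]]),
                     stringsAsFactors = FALSE)
  } else {
    format_error("format error in '", path,
                 "': expected columns kinase, substrate, site, effect ",
                 "or the three-column SIF layout")
  }
  as_ks_relations(df, aliases = aliases, origin = path)
}

#' Validate a kinase-substrate relation data frame
#'
#' @param df Data frame with columns `kinase`, `substrate`, `site`, `effect`.
#' @inheritParams as_probe_table
#' @return A validated `ks_relations`.
#' @export
as_ks_relations <- function(df, aliases = NULL, origin = "relation table") {
  for (col in RELATION_COLUMNS) df[[col]] <- as.character(df[[col]])
  df$kinase <- apply_aliases(toupper(df$kinase), aliases)
  df$substrate <- apply_aliases(toupper(df$substrate), aliases)
  df$effect <- tolower(df$effect)
  badeff <- which(!df$effect %in% EFFECT_LEVELS)
  if (length(badeff) > 0) {
    format_error("format error in ", origin, ": unknown effect '",
                 df$effect[badeff[1]], "' at row ", badeff[1],
                 " (expected activation/inhibition/unknown)")
  }
  empty <- which(!nzchar(df$kinase) | !nzchar(df$substrate))
  if (length(empty) > 0) {
    format_error("validation error in ", origin,
                 ": empty kinase or substrate at row ", empty[1])
  }
  badsite <- which(!site_is_valid(df$site))
  if (length(badsite) > 0) {
    format_error("validation error in ", origin, ": invalid site '",
                 df$site[badsite[1]], "' at row ", badsite[1])
  }
  key <- paste(df$kinase, df$substrate, df$site, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    format_error("validation error in ", origin, ": duplicate relation ",
                 df$kinase[dup[1]], " -> ", df$substrate[dup[1]], "@",
                 df$site[dup[1]], " at row ", dup[1])
  }
  rownames(df) <- NULL
  structure(df[RELATION_COLUMNS], class = c("ks_relations", "data.frame"))
}

#' Write a kinase-substrate relation table
#'
#' @param x A `ks_relations` data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_ks_relations <- function(x, path, sep = "\t") {
  utils::write.table(as.data.frame(x)[RELATION_COLUMNS], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Write a lead table
#'
#' Summarises selected phosphorylation chains into one row per distinct
#' *measured* phosphosite appearing in any chain (the "leads"): target, site,
#' direction (`up`/`down`), measured percent change from control, and the
#' number of chains containing the site. Rows are sorted by target then site.
#'
#' @param chains A list of `phospho_chain` objects (see
#'   [infer_direction_run()]); may mix directions.
#' @param path Output path.
#' @param sep Field separator.
#' @return Invisibly, the lead table data frame.
#' @export
write_lead_table <- function(chains, path, sep = "\t") {
  leads <- lead_table(chains)
  utils::write.table(leads, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(leads)
}

#' Build a lead table from chains
#'
#' @inheritParams write_lead_table
#' @return Data frame with columns `target`, `site`, `direction`,
#'   `cfc_percent`, `n_chains`.
#' @export
lead_table <- function(chains) {
  rows <- list()
  for (ch in chains) {
    ed <- ch$edges
    measured <- which(!is.na(ed$cfc) & !ed$imputed)
    if (length(measured) == 0) next
    r <- data.frame(
      target = ed$substrate[measured],
      site = ed$site[measured],
      direction = ch$direction,
      cfc_percent = ed$cfc[measured],
      stringsAsFactors = FALSE)
    # count each site at most once per chain
    r <- r[!duplicated(paste(r$target, r$site, sep = "\r")), , drop = FALSE]
    rows[[length(rows) + 1L]] <- r
  }
  if (length(rows) == 0) {
    return(data.frame(target = character(), site = character(),
                      direction = character(), cfc_percent = numeric(),
                      n_chains = integer(), stringsAsFactors = FALSE))
  }
  all_rows <- do.call(rbind, rows)
  key <- paste(all_rows$target, all_rows$site, all_rows$direction, sep = "\r")
  # a site may be delivered by several edges within one chain set; count chains
  counts <- tapply(key, key, length)
  first <- !duplicated(key)
  out <- all_rows[first, , drop = FALSE]
  out$n_chains <- as.integer(counts[paste(out$target, out$site, out$direction,
                                          sep = "\r")])
  out <- out[order(out$target, out$site, out$direction, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
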