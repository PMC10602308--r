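# Signed directed kinase-substrate network: construction from relation
# tables, attachment of measured %CFC values to edges, root identification,
# and the split into up- and down-regulated subnetworks.
#
# A signed_network holds its edges as a data frame (one row per
# (kinase, substrate, site) relation) with per-edge measurement columns:
#   effect  - "activation" or "inhibition" (no "unknown" survives construction)
#   cfc     - signed measured %CFC of the substrate site (NA if unmeasured)
#   weight  - nonnegative walk weight: |cfc| when measured, an imputed value
#             for single-path edges, else 0
#   imputed - TRUE when weight/cfc came from single-path imputation

#' Build a signed kinase-substrate network
#'
#' One directed edge per relation. Relations with effect `"unknown"` (no
#' known biological consequence) are coerced to `"activation"`; nodes are the
#' union of kinases and substrates. Cycles are permitted at this stage.
#'
#' @param relations A `ks_relations` data frame (see [read_ks_relations()]).
#' @return An object of class `signed_network`.
#' @export
build_network <- function(relations) {
  relations <- as.data.frame(relations)
  n <- nrow(relations)
  effect <- ifelse(relations$effect == "unknown", "activation",
                   relations$effect)
  edges <- data.frame(
    kinase = as.character(relations$kinase),
    substrate = as.character(relations$substrate),
    site = as.character(relations$site),
    effect = as.character(effect),
    cfc = rep(NA_real_, n),
    weight = rep(0, n),
    imputed = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  new_signed_network(edges)
}

new_signed_network <- function(edges, node_log2fc = numeric(0),
                               direction = NA_character_, pool = NULL) {
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$kinase, edges$substrate)), method = "radix")
  structure(list(edges = edges, nodes = nodes,
                 node_log2fc = node_log2fc,
                 direction = direction,
                 pool = pool),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  n_meas <- sum(!is.na(x$edges$cfc))
  cat(sprintf("<signed_network> %d nodes, %d edges (%d measured, %d inhibitory)%s\n",
              length(x$nodes), nrow(x$edges), n_meas,
              sum(x$edges$effect == "inhibition"),
              if (!is.na(x$direction)) paste0(", direction: ", x$direction) else ""))
  invisible(x)
}

#' Root kinases of a network
#'
#' The nodes with no directed edge toward them (in-degree zero). Because the
#' array does not report which kinase performed each phosphorylation, these
#' are taken as the most probable start points of downstream phosphorylation
#' chains, and walks start only from them.
#'
#' @param network A `signed_network`.
#' @return Character vector of node names (sorted).
#' @export
find_roots <- function(network) {
  setdiff(network$nodes, unique(network$edges$substrate))
}

#' Attach probe measurements to a network
#'
#' Phosphosite-specific probes set the `cfc` and `weight` of *every* edge
#' delivering phosphorylation to the matching `(substrate, site)` (the array
#' cannot attribute the event to one upstream kinase). Pan-specific probes
#' annotate node expression (`log2fc`) only and never weight edges: chain
#' inference is defined over phosphorylation events, not expression. Probes
#' matching no edge are returned as `unmapped`.
#'
#' @param network A `signed_network` from [build_network()].
#' @param measurements A preprocessed `probe_table` (filters applied,
#'   `cfc_percent` and `log2fc` present, see [preprocess_pipeline()]).
#' @return The network with measurements attached; attribute `unmapped`
#'   holds the probe ids that matched nothing.
#' @export
attach_measurements <- function(network, measurements) {
  stopifnot(inherits(network, "signed_network"),
            "cfc_percent" %in% names(measurements))
  edges <- network$edges
  is_pan <- measurements$site == "pan"
  phospho <- measurements[!is_pan, , drop = FALSE]

  pkey <- paste(phospho$target, phospho$site, sep = "@")
  dup <- unique(pkey[duplicated(pkey)])
  if (length(dup) > 0) {
    offending <- phospho$probe_id[pkey %in% dup]
    stop("ambiguity error: multiple retained probes map to the same site(s) ",
         paste(dup, collapse = ", "), " (probes: ",
         paste(offending, collapse = ", "), ")", call. = FALSE)
  }
  ekey <- paste(edges$substrate, edges$site, sep = "@")
  idx <- match(ekey, pkey)
  hit <- !is.na(idx)
  edges$cfc[hit] <- phospho$cfc_percent[idx[hit]]
  edges$weight[hit] <- abs(phospho$cfc_percent[idx[hit]])
  edges$imputed[hit] <- FALSE

  node_log2fc <- network$node_log2fc
  pan <- measurements[is_pan, , drop = FALSE]
  pan <- pan[pan$target %in% network$nodes, , drop = FALSE]
  if (nrow(pan) > 0) {
    node_log2fc[pan$target] <- pan$log2fc
  }
  unmapped <- c(phospho$probe_id[!pkey %in% ekey],
                measurements$probe_id[is_pan][
                  !measurements$target[is_pan] %in% network$nodes])
  out <- new_signed_network(edges, node_log2fc = node_log2fc)
  attr(out, "unmapped") <- unmapped
  out
}

#' Split a measured network into up- and down-regulated subnetworks
#'
#' The up subnetwork keeps edges with measured `cfc > 0` or no measurement;
#' the down subnetwork keeps edges with `cfc < 0` or no measurement. Edges
#' measured exactly 0 are neither up- nor down-regulated and are excluded
#' from both. Each subnetwork retains all nodes incident to its kept edges
#' and remembers the full measured network (its "pool") so that the
#' permutation null can reassign measured values network-wide.
#'
#' @param network A measured `signed_network` (see [attach_measurements()]).
#' @return List with components `up` and `down`, each a `signed_network`.
#' @export
split_signed <- function(network) {
  # fix edge identities on the full network first so that subnetwork chains
  # and permutation-null chains share one edge-id space
  if (is.null(network$edges$edge_id)) {
    network$edges$edge_id <- seq_len(nrow(network$edges))
  }
  edges <- network$edges
  keep_dir <- function(dir) {
    keep <- if (dir == "up") {
      is.na(edges$cfc) | edges$cfc > 0
    } else {
      is.na(edges$cfc) | edges$cfc < 0
    }
    sub <- new_signed_network(edges[keep, , drop = FALSE],
                              node_log2fc = network$node_log2fc,
                              direction = dir,
                              pool = network)
    sub
  }
  list(up = keep_dir("up"), down = keep_dir("down"))
}

#' Convert a signed network to an igraph graph
#'
#' Edge attributes: `site`, `effect`, `cfc`, `weight`, `imputed`.
#'
#' @param network A `signed_network`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(network) {
  e <- network$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$kinase, to = e$substrate,
               site = e$site, effect = e$effect,
               cfc = ifelse(is.na(e$cfc), NaN, e$cfc),
               weight = e$weight, imputed = e$imputed,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  g
}

#' Export a signed network
#'
#' @param network A `signed_network`.
#' @param path Output path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(network$edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(NULL)
}

#' Import a signed network edge list
#'
#' Reads back the TSV edge-list written by [export_network()].
#'
#' @param path Path to the edge-list TSV.
#' @return A `signed_network`.
#' @export
import_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("kinase", "substrate", "site", "effect")
  if (!all(need %in% names(df))) {
    stop("format error in '", path, "': expected edge-list columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$cfc)) df$cfc <- NA_real_
  if (is.null(df$weight)) df$weight <- ifelse(is.na(df$cfc), 0, abs(df$cfc))
  if (is.null(df$imputed)) df$imputed <- FALSE
  new_signed_network(df[c("kinase", "substrate", "site", "effect",
                          "cfc", "weight", "imputed")])
}
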