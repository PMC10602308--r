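# Assembly of selected up- and down-direction chains into one comparative
# pathway map, with log2-fold-change derived styling and export to
# GraphML / DOT / JSON.

#' Assemble a comparative pathway map
#'
#' Takes the union of all edges of the selected chains from both directions,
#' tagging each edge with its direction. Duplicate `(kinase, substrate,
#' site)` edges are merged once; an edge appearing in chains of both
#' directions keeps the version with the greater |log2 fold change|
#' (mirroring the parallel-magnitude rule). Per-edge `log2fc` is derived
#' from the signed CFC as `log2(1 + cfc/100)`.
#'
#' @param up_chains,down_chains Lists of selected `phospho_chain`s.
#' @return An object of class `pathway_map` with a `nodes` vector and an
#'   `edges` data frame (`kinase`, `substrate`, `site`, `effect`, `cfc`,
#'   `log2fc`, `direction`, `imputed`).
#' @export
assemble_map <- function(up_chains, down_chains = list()) {
  collect <- function(chains, direction) {
    if (length(chains) == 0) return(NULL)
    ed <- do.call(rbind, lapply(chains, function(ch)
      ch$edges[c("kinase", "substrate", "site", "effect", "cfc", "weight",
                 "imputed")]))
    ed$direction <- direction
    ed
  }
  edges <- rbind(collect(up_chains, "up"), collect(down_chains, "down"))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(kinase = character(), substrate = character(),
                        site = character(), effect = character(),
                        cfc = numeric(), log2fc = numeric(),
                        direction = character(), imputed = logical(),
                        stringsAsFactors = FALSE)
    return(structure(list(nodes = character(), edges = edges),
                     class = "pathway_map"))
  }
  cfc_floor <- pmax(edges$cfc, -99.9) # keep log2 finite for full knock-downs
  edges$log2fc <- ifelse(is.na(edges$cfc), 0, log2(1 + cfc_floor / 100))
  key <- paste(edges$kinase, edges$substrate, edges$site, sep = "\r")
  # within a key, keep the row with the greatest |log2fc| (direction merge)
  ord <- order(key, -abs(edges$log2fc), edges$direction, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$kinase, edges$substrate, edges$site,
                                   sep = "\r")), , drop = FALSE]
  edges <- edges[order(edges$kinase, edges$substrate, edges$site,
                       method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$kinase, edges$substrate)), method = "radix")
  structure(list(nodes = nodes,
                 edges = edges[c("kinase", "substrate", "site", "effect",
                                 "cfc", "log2fc", "direction", "imputed")]),
            class = "pathway_map")
}

#' @export
print.pathway_map <- function(x, ...) {
  cat(sprintf("<pathway_map> %d nodes, %d edges (%d up, %d down)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$direction == "up"),
              sum(x$edges$direction == "down")))
  invisible(x)
}

#' Style map edges by log2 fold change
#'
#' Arrow width interpolates |log2fc| linearly into `width_range` (all widths
#' equal to the midpoint when every |log2fc| is identical); the color class
#' is the sign of the change (`"up"` / `"down"`), left symbolic so renderers
#' can pick their own palette.
#'
#' @param map A `pathway_map`.
#' @param width_range Numeric `(min, max)` drawing widths, default
#'   `c(0.5, 4)`.
#' @return The map with `width` and `color_class` columns added.
#' @export
style_edges <- function(map, width_range = c(0.5, 4)) {
  stopifnot(inherits(map, "pathway_map"), length(width_range) == 2,
            width_range[2] >= width_range[1])
  ed <- map$edges
  if (nrow(ed) == 0) {
    ed$width <- numeric(0)
    ed$color_class <- character(0)
    map$edges <- ed
    return(map)
  }
  mag <- abs(ed$log2fc)
  span <- max(mag) - min(mag)
  frac <- if (span == 0) rep(0.5, length(mag)) else (mag - min(mag)) / span
  ed$width <- width_range[1] + frac * (width_range[2] - width_range[1])
  ed$color_class <- ed$direction
  map$edges <- ed
  map
}

#' Export a pathway map
#'
#' GraphML and JSON exports round-trip all attributes (see [import_map()]);
#' DOT carries the style attributes for rendering with standard graph layout
#' tools. Element order is stable.
#'
#' @param map A `pathway_map` (styled or not).
#' @param path Output path.
#' @param format One of `"graphml"`, `"dot"`, `"json"`.
#' @export
export_map <- function(map, path, format = c("graphml", "dot", "json")) {
  if (!format[1] %in% c("graphml", "dot", "json")) {
    stop("parameter error: unknown map format '", format[1], "'",
         call. = FALSE)
  }
  format <- match.arg(format)
  ed <- map$edges
  if (format == "graphml") {
    if (nrow(ed) == 0 && length(map$nodes) == 0) {
      g <- igraph::make_empty_graph(directed = TRUE)
    } else {
      df <- data.frame(from = ed$kinase, to = ed$substrate,
                       site = ed$site, effect = ed$effect,
                       cfc = ifelse(is.na(ed$cfc), NaN, ed$cfc),
                       log2fc = ed$log2fc, direction = ed$direction,
                       imputed = ed$imputed, stringsAsFactors = FALSE)
      if (!is.null(ed$width)) {
        df$width <- ed$width
        df$color_class <- ed$color_class
      }
      g <- igraph::graph_from_data_frame(df, directed = TRUE,
                                         vertices = data.frame(name = map$nodes))
    }
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "json") {
    jsonlite::write_json(list(nodes = map$nodes, edges = ed), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
  } else {
    lines <- c("digraph pathway_map {", "  rankdir=LR;")
    for (n in map$nodes) {
      lines <- c(lines, sprintf("  \"%s\";", n))
    }
    for (i in seq_len(nrow(ed))) {
      w <- if (!is.null(ed$width)) ed$width[i] else 1
      color <- if (identical(ed$direction[i], "up")) "red" else "blue"
      arrow <- if (ed$effect[i] == "inhibition") "tee" else "normal"
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [label=\"%s\", penwidth=%.3f, color=%s, arrowhead=%s];",
        ed$kinase[i], ed$substrate[i], ed$site[i], w, color, arrow))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(NULL)
}

#' Import a pathway map
#'
#' Reads back a `"graphml"` or `"json"` export of [export_map()].
#'
#' @param path Path to the exported file.
#' @param format `"graphml"` or `"json"`.
#' @return A `pathway_map`.
#' @export
import_map <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(g)$name
    if (igraph::ecount(g) == 0) {
      ed <- data.frame(kinase = character(), substrate = character(),
                       site = character(), effect = character(),
                       cfc = numeric(), log2fc = numeric(),
                       direction = character(), imputed = logical(),
                       stringsAsFactors = FALSE)
    } else {
      ends <- igraph::as_edgelist(g)
      ed <- data.frame(kinase = ends[, 1], substrate = ends[, 2],
                       site = igraph::E(g)$site,
                       effect = igraph::E(g)$effect,
                       cfc = igraph::E(g)$cfc,
                       log2fc = igraph::E(g)$log2fc,
                       direction = igraph::E(g)$direction,
                       imputed = as.logical(igraph::E(g)$imputed),
                       stringsAsFactors = FALSE)
      ed$cfc[is.nan(ed$cfc)] <- NA_real_
      if (!is.null(igraph::E(g)$width)) {
        ed$width <- igraph::E(g)$width
        ed$color_class <- igraph::E(g)$color_class
      }
      ed <- ed[order(ed$kinase, ed$substrate, ed$site, method = "radix"), ,
               drop = FALSE]
      rownames(ed) <- NULL
    }
    structure(list(nodes = sort(nodes, method = "radix"), edges = ed),
              class = "pathway_map")
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    ed <- as.data.frame(j$edges, stringsAsFactors = FALSE)
    if (is.null(ed$cfc)) ed$cfc <- numeric(nrow(ed))
    structure(list(nodes = as.character(j$nodes), edges = ed),
              class = "pathway_map")
  }
}
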