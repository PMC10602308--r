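# Inference of phosphorylation chains by seeded random walks.
#
# A chain is a root-anchored, edge-self-avoiding path of phosphorylation
# events. Walks step to an untraversed outgoing edge with probability
# proportional to (walk weight + epsilon); a chain terminates when the last
# edge is inhibitory, when no untraversed outgoing edge remains, or at a
# configurable maximum length. Observed chain frequencies are compared with a
# permutation null that reassigns the measured site values across the
# network, and chains occurring clearly more or less frequently than
# expected are carried into parallel-phosphorylation resolution and
# depth/effect-size selection.

#' Inference configuration
#'
#' @param n_walks Number of random walks per direction for the observed
#'   frequencies.
#' @param n_permutations Number of label permutations for the null.
#' @param null_walks Walks per permutation; expected frequencies are averaged
#'   over `n_permutations * null_walks` null walks in total.
#' @param seed Integer seed; every stage derives its own stream from it.
#' @param epsilon Additive smoothing (percent points) on walk weights so that
#'   unmeasured edges stay reachable.
#' @param enrichment_hi,enrichment_lo Keep chains with
#'   `enrichment >= enrichment_hi` (over-represented) or
#'   `<= enrichment_lo` (under-represented).
#' @param alpha Evidence level for the enrichment call: a chain is only
#'   called over-/under-represented when its observed walk count is
#'   incompatible with the null expectation by a binomial test at
#'   Benjamini-Hochberg adjusted `alpha`. The ratio thresholds define the
#'   effect size of interest; the test guards against Poisson noise on
#'   rarely visited chains.
#' @param min_intermediates Exclusive lower bound on the number of internal
#'   nodes of a selected chain (default: more than 2 intermediates). Set to
#'   a negative value to disable.
#' @param min_cfc Exclusive lower bound (percent) on every measured-or-imputed
#'   per-edge |CFC| of a selected chain.
#' @param cfc_mode `"all"` applies `min_cfc` to every measured-or-imputed
#'   edge; `"mean"` applies it to their mean magnitude.
#' @param max_length Maximum edges per walk (guarantees termination on
#'   cyclic inputs).
#' @param impute `"uniform"` draws experimental single-path imputations
#'   uniformly in \[0, 20\] percent; `"fixed"` uses the midpoint 10.
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(n_walks = 10000, n_permutations = 200,
                        null_walks = 2000, seed = 1, epsilon = 1,
                        enrichment_hi = 1.5, enrichment_lo = 0.67,
                        alpha = 0.05,
                        min_intermediates = 2, min_cfc = 5,
                        cfc_mode = c("all", "mean"),
                        max_length = 25,
                        impute = c("uniform", "fixed")) {
  if (n_walks < 1) stop("parameter error: n_walks must be >= 1", call. = FALSE)
  if (n_permutations < 1) {
    stop("parameter error: n_permutations must be >= 1", call. = FALSE)
  }
  if (enrichment_hi < enrichment_lo) {
    stop("config validation error: enrichment_hi must be >= enrichment_lo",
         call. = FALSE)
  }
  structure(list(n_walks = as.integer(n_walks),
                 n_permutations = as.integer(n_permutations),
                 null_walks = as.integer(null_walks),
                 seed = as.integer(seed),
                 epsilon = epsilon,
                 enrichment_hi = enrichment_hi,
                 enrichment_lo = enrichment_lo,
                 alpha = alpha,
                 min_intermediates = min_intermediates,
                 min_cfc = min_cfc,
                 cfc_mode = match.arg(cfc_mode),
                 max_length = as.integer(max_length),
                 impute = match.arg(impute)),
            class = "walk_config")
}

# Deterministic per-stage seed fan-out from one global seed.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

edge_ids <- function(network) {
  if (is.null(network$edges$edge_id)) seq_len(nrow(network$edges))
  else network$edges$edge_id
}

with_edge_ids <- function(network) {
  if (is.null(network$edges$edge_id)) {
    network$edges$edge_id <- seq_len(nrow(network$edges))
  }
  network
}

#' Termination check for a growing chain
#'
#' Returns `"inhibition"` if the last traversed edge is inhibitory,
#' `"sink"` if the terminal node has no untraversed outgoing edge, and
#' `"continue"` otherwise.
#'
#' @param current_chain A `phospho_chain` (or a data frame of traversed edge
#'   rows with columns `kinase`, `substrate`, `site`, `effect`).
#' @param network The `signed_network` being walked.
#' @return One of `"continue"`, `"sink"`, `"inhibition"`.
#' @export
check_termination <- function(current_chain, network) {
  ed <- if (inherits(current_chain, "phospho_chain")) current_chain$edges
        else current_chain
  if (nrow(ed) == 0) stop("chain must be nonempty", call. = FALSE)
  last <- ed[nrow(ed), ]
  if (last$effect == "inhibition") return("inhibition")
  all_e <- network$edges
  trav <- paste(ed$kinase, ed$substrate, ed$site, sep = "\r")
  outgoing <- all_e[all_e$kinase == last$substrate, , drop = FALSE]
  fresh <- !paste(outgoing$kinase, outgoing$substrate, outgoing$site,
                  sep = "\r") %in% trav
  if (any(fresh)) "continue" else "sink"
}

#' Single-path fold-change imputation
#'
#' When a node has exactly one downstream option and that edge carries no
#' measured change, the walk still needs a magnitude for it: the control
#' condition is assigned exactly 20 percent, the experimental condition a
#' seeded uniform draw between 0 and 20 percent (or the fixed midpoint 10
#' when `fixed = TRUE`). Imputed values are flagged as such wherever they
#' appear downstream.
#'
#' @param node Gene symbol with exactly one outgoing, unmeasured edge.
#' @param network A `signed_network`.
#' @param condition `"experimental"` or `"control"`.
#' @param rng_seed Integer seed for the experimental draw.
#' @param fixed Use the midpoint 10 instead of a draw.
#' @return Imputed percent fold change.
#' @export
impute_single_path <- function(node, network,
                               condition = c("experimental", "control"),
                               rng_seed = 1, fixed = FALSE) {
  condition <- match.arg(condition)
  out <- which(network$edges$kinase == node)
  if (length(out) != 1L) {
    stop("not applicable: node '", node, "' has ", length(out),
         " downstream options (single-path imputation needs exactly 1)",
         call. = FALSE)
  }
  if (!is.na(network$edges$cfc[out])) {
    stop("not applicable: the single downstream edge of '", node,
         "' already carries a measured change", call. = FALSE)
  }
  if (condition == "control") return(20)
  if (fixed) return(10)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(rng_seed)
  stats::runif(1, 0, 20)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Apply single-path imputation across a direction subnetwork: every node with
# exactly one outgoing edge whose edge is unmeasured receives an imputed
# weight. Imputed cfc is signed by the network direction so that selection
# can treat imputed and measured magnitudes uniformly.
impute_network <- function(network, condition = "experimental", seed = 1,
                           fixed = FALSE) {
  edges <- network$edges
  outdeg <- table(edges$kinase)
  single <- names(outdeg)[outdeg == 1]
  idx <- which(edges$kinase %in% single & is.na(edges$cfc))
  if (length(idx) == 0) return(network)
  idx <- idx[order(edges$kinase[idx], method = "radix")]
  vals <- if (condition == "control") {
    rep(20, length(idx))
  } else if (fixed) {
    rep(10, length(idx))
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    stats::runif(length(idx), 0, 20)
  }
  sgn <- if (identical(network$direction, "down")) -1 else 1
  edges$cfc[idx] <- sgn * vals
  edges$weight[idx] <- vals
  edges$imputed[idx] <- TRUE
  network$edges <- edges
  network
}

#' Exact chain distribution by enumeration
#'
#' Brute-force counterpart of [random_walk()]: enumerates every
#' root-to-termination chain together with its exact probability under the
#' walk's transition rule. Intended as an oracle on small networks;
#' probabilities sum to 1.
#'
#' @param network A `signed_network`.
#' @param max_length Maximum chain length in edges.
#' @param epsilon Additive weight smoothing, as in [random_walk()].
#' @param max_chains Abort if more than this many chains are generated.
#' @return Data frame with columns `key` (dash-joined edge ids) and `prob`.
#' @export
enumerate_chains <- function(network, max_length = 25, epsilon = 1,
                             max_chains = 1e5) {
  network <- with_edge_ids(network)
  edges <- network$edges
  if (nrow(edges) == 0) {
    return(data.frame(key = character(), prob = numeric(),
                      stringsAsFactors = FALSE))
  }
  roots <- find_roots(network)
  if (length(roots) == 0) {
    stop("rootless network: every node has an incoming edge", call. = FALSE)
  }
  out_by_node <- split(seq_len(nrow(edges)), edges$kinase)
  keys <- character()
  probs <- numeric()
  emit <- function(path, p) {
    if (length(keys) >= max_chains) {
      stop("enumeration exceeded max_chains = ", max_chains, call. = FALSE)
    }
    keys[[length(keys) + 1L]] <<- paste(edges$edge_id[path], collapse = "-")
    probs[[length(probs) + 1L]] <<- p
  }
  recurse <- function(node, path, used, p) {
    cand <- setdiff(out_by_node[[node]], NULL)
    if (!is.null(cand)) cand <- cand[!used[cand]]
    if (is.null(cand) || length(cand) == 0) {
      emit(path, p)
      return(invisible())
    }
    w <- edges$weight[cand] + epsilon
    w <- w / sum(w)
    for (i in seq_along(cand)) {
      e <- cand[i]
      used[e] <- TRUE
      path2 <- c(path, e)
      if (edges$effect[e] == "inhibition" || length(path2) >= max_length) {
        emit(path2, p * w[i])
      } else {
        recurse(edges$substrate[e], path2, used, p * w[i])
      }
      used[e] <- FALSE
    }
  }
  p0 <- 1 / length(roots)
  for (r in roots) {
    recurse(r, integer(0), logical(nrow(edges)), p0)
  }
  agg <- tapply(probs, keys, sum)
  out <- data.frame(key = names(agg), prob = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[out$key != "", , drop = FALSE]
  out <- out[order(out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Low-level walk driver shared by random_walk() and the permutation null.
walk_network <- function(network, n_walks, max_length, epsilon) {
  network <- with_edge_ids(network)
  edges <- network$edges
  if (nrow(edges) == 0) return(stats::setNames(integer(0), character(0)))
  roots <- find_roots(network)
  if (length(roots) == 0) {
    stop("rootless network: every node has an incoming edge", call. = FALSE)
  }
  node_idx <- stats::setNames(seq_along(network$nodes) - 1L, network$nodes)
  counts <- .walk_counts(length(network$nodes),
                         as.integer(node_idx[edges$kinase]),
                         as.integer(node_idx[edges$substrate]),
                         as.numeric(edges$weight),
                         edges$effect == "inhibition",
                         as.integer(edges$edge_id),
                         as.integer(node_idx[roots]),
                         as.integer(n_walks),
                         as.integer(max_length),
                         epsilon)
  counts[names(counts) != ""]
}

#' Observed chain frequencies from seeded random walks
#'
#' Runs `n_walks` edge-self-avoiding random walks from uniformly chosen
#' roots, with transition probability proportional to `weight + epsilon`,
#' and tabulates complete chains. Fully reproducible from `seed`.
#'
#' @param network A `signed_network` (weights attached/imputed as desired).
#' @param n_walks Number of walks (>= 1).
#' @param seed Integer seed.
#' @param epsilon Additive weight smoothing.
#' @param max_length Maximum edges per walk.
#' @return A `walk_estimate`: data frame `chains` with `key` and
#'   `observed` frequency plus run metadata.
#' @export
random_walk <- function(network, n_walks, seed = 1, epsilon = 1,
                        max_length = 25) {
  if (n_walks < 1) stop("parameter error: n_walks must be >= 1", call. = FALSE)
  network <- with_edge_ids(network)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  counts <- walk_network(network, n_walks, max_length, epsilon)
  chains <- data.frame(key = names(counts),
                       observed = as.numeric(counts) / n_walks,
                       stringsAsFactors = FALSE)
  chains <- chains[order(chains$key, method = "radix"), , drop = FALSE]
  rownames(chains) <- NULL
  structure(list(chains = chains, n_walks = as.integer(n_walks),
                 n_permutations = 0L, null_walks = 0L,
                 seed = as.integer(seed), network = network),
            class = "walk_estimate")
}

#' @export
print.walk_estimate <- function(x, ...) {
  cat(sprintf("<walk_estimate> %d chains from %d walks%s\n",
              nrow(x$chains), x$n_walks,
              if (x$n_permutations > 0)
                sprintf(", null: %d permutations x %d walks",
                        x$n_permutations, x$null_walks) else ""))
  invisible(x)
}

# One null replicate: reassign the measured site-level CFC values uniformly
# at random across the measured sites of the pool network, re-derive the
# direction subnetwork, and keep the observed network's imputations.
permute_pool <- function(pool, direction, imputed_edges) {
  edges <- pool$edges
  skey <- paste(edges$substrate, edges$site, sep = "@")
  measured_sites <- !duplicated(skey) & !is.na(edges$cfc)
  site_names <- skey[measured_sites]
  site_vals <- edges$cfc[measured_sites]
  perm <- sample.int(length(site_vals))
  new_vals <- stats::setNames(site_vals[perm], site_names)
  idx <- match(skey, site_names)
  edges$cfc <- ifelse(is.na(idx), NA_real_, new_vals[idx])
  edges$weight <- ifelse(is.na(edges$cfc), 0, abs(edges$cfc))
  edges$imputed <- FALSE
  keep <- if (direction == "up") is.na(edges$cfc) | edges$cfc > 0
          else is.na(edges$cfc) | edges$cfc < 0
  sub <- edges[keep, , drop = FALSE]
  # carry over the imputations made on the observed direction network
  if (nrow(imputed_edges) > 0) {
    m <- match(sub$edge_id, imputed_edges$edge_id)
    hit <- !is.na(m) & is.na(sub$cfc)
    sub$cfc[hit] <- imputed_edges$cfc[m[hit]]
    sub$weight[hit] <- imputed_edges$weight[m[hit]]
    sub$imputed[hit] <- TRUE
  }
  new_signed_network(sub, direction = direction)
}

#' Permutation-null expected frequencies and enrichment
#'
#' Estimates, for every chain observed by [random_walk()], how often it would
#' arise if the measured site changes were placed on the network at random:
#' the measured site-level CFC values are permuted among the measured sites,
#' the direction subnetwork is re-derived, and walks are rerun. When the
#' network was produced by [split_signed()] the permutation acts on the full
#' measured network (its pool) so that sign reassignment can rewire the
#' subnetwork; a standalone network permutes its own measured values in
#' place. `enrichment = observed / expected`; chains never seen under the
#' null receive the pseudo-floor expectation
#' `1 / (null_walks * n_permutations)`.
#'
#' @param network A measured (and optionally imputed) `signed_network`.
#' @param n_walks Walks for the observed frequencies.
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param null_walks Walks per permutation (default `n_walks`).
#' @param epsilon,max_length As in [random_walk()].
#' @return A `walk_estimate` with `expected` and `enrichment` columns filled.
#' @export
null_expectation <- function(network, n_walks, n_permutations, seed = 1,
                             null_walks = n_walks, epsilon = 1,
                             max_length = 25) {
  if (n_permutations < 1) {
    stop("parameter error: n_permutations must be >= 1", call. = FALSE)
  }
  network <- with_edge_ids(network)
  est <- random_walk(network, n_walks, seed = seed, epsilon = epsilon,
                     max_length = max_length)
  if (nrow(est$chains) == 0) {
    est$chains$expected <- numeric(0)
    est$chains$enrichment <- numeric(0)
    return(est)
  }
  direction <- network$direction
  pool <- network$pool
  imputed_edges <- network$edges[network$edges$imputed, , drop = FALSE]

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, "null"))
  null_counts <- stats::setNames(numeric(nrow(est$chains)), est$chains$key)
  for (p in seq_len(n_permutations)) {
    perm_net <- if (!is.null(pool)) {
      permute_pool(with_edge_ids(pool), direction, imputed_edges)
    } else {
      # in-place magnitude permutation among this network's measured edges
      e <- network$edges
      meas <- which(!is.na(e$cfc) & !e$imputed)
      if (length(meas) < 2) {
        stop("null expectation needs at least 2 measured edges", call. = FALSE)
      }
      e$weight[meas] <- e$weight[meas][sample.int(length(meas))]
      net2 <- network
      net2$edges <- e
      net2
    }
    cnt <- tryCatch(walk_network(perm_net, null_walks, max_length, epsilon),
                    error = function(err) integer(0))
    if (length(cnt) > 0) {
      hit <- intersect(names(cnt), names(null_counts))
      null_counts[hit] <- null_counts[hit] + cnt[hit]
    }
  }
  expected <- as.numeric(null_counts) / (n_permutations * null_walks)
  floor_val <- 1 / (as.numeric(null_walks) * n_permutations)
  expected[expected == 0] <- floor_val
  est$chains$expected <- expected
  est$chains$enrichment <- est$chains$observed / expected
  est$n_permutations <- as.integer(n_permutations)
  est$null_walks <- as.integer(null_walks)
  est
}

# Decode a chain key into a phospho_chain object.
chain_from_key <- function(key, network, max_length = 25,
                           observed = NA_real_, expected = NA_real_,
                           enrichment = NA_real_) {
  ids <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
  rows <- match(ids, edge_ids(network))
  ed <- network$edges[rows, , drop = FALSE]
  rownames(ed) <- NULL
  n_edges <- nrow(ed)
  last_inhib <- ed$effect[n_edges] == "inhibition"
  reason <- if (last_inhib) {
    "inhibition"
  } else {
    terminal <- ed$substrate[n_edges]
    fresh <- network$edges$kinase == terminal &
      !edge_ids(network) %in% ids
    if (any(fresh) && n_edges >= max_length) "max_length" else "sink"
  }
  structure(list(
    key = key,
    edges = ed,
    direction = if (is.na(network$direction)) "up" else network$direction,
    per_edge_cfc = ed$cfc,
    imputed = ed$imputed,
    n_intermediates = n_edges - 1L,
    termination_reason = reason,
    score = min(ed$weight),
    observed = observed, expected = expected, enrichment = enrichment
  ), class = "phospho_chain")
}

#' @export
print.phospho_chain <- function(x, ...) {
  ed <- x$edges
  path <- paste0(ed$kinase[1],
                 paste0(ifelse(ed$effect == "inhibition", " -| ", " -> "),
                        ed$substrate, "@", ed$site, collapse = ""))
  cat(sprintf("<phospho_chain %s> %s\n  intermediates: %d, score: %.3g, ends by %s\n",
              x$direction, path, x$n_intermediates, x$score,
              x$termination_reason))
  invisible(x)
}

#' Build chain objects from a walk estimate
#'
#' @param estimate A `walk_estimate`.
#' @param max_length Maximum walk length used (for termination labelling).
#' @return List of `phospho_chain` objects, in key order.
#' @export
chains_from_estimate <- function(estimate, max_length = 25) {
  ch <- estimate$chains
  lapply(seq_len(nrow(ch)), function(i) {
    chain_from_key(ch$key[i], estimate$network, max_length = max_length,
                   observed = ch$observed[i],
                   expected = if (!is.null(ch$expected)) ch$expected[i] else NA_real_,
                   enrichment = if (!is.null(ch$enrichment)) ch$enrichment[i] else NA_real_)
  })
}

#' Resolve parallel phosphorylation events
#'
#' When two or more chains deliver phosphorylation to the same
#' `(substrate, site)` via different immediate kinases, only the chains whose
#' delivering edge carries the greatest magnitude are kept for that site;
#' ties keep all chains. Different sites on the same substrate are not
#' compared. Output is sorted by the first kinase of each chain, then key.
#'
#' @param chains List of `phospho_chain`s from one direction.
#' @return Filtered, deterministically ordered list of `phospho_chain`s.
#' @export
resolve_parallel <- function(chains) {
  if (length(chains) == 0) return(chains)
  # collect delivering edges: (substrate, site, kinase, weight) per chain
  best <- new.env(parent = emptyenv())
  for (ch in chains) {
    ed <- ch$edges
    for (i in seq_len(nrow(ed))) {
      k <- paste(ed$substrate[i], ed$site[i], sep = "@")
      rec <- get0(k, envir = best)
      if (is.null(rec)) {
        assign(k, list(w = ed$weight[i], kinases = ed$kinase[i]), envir = best)
      } else {
        rec$kinases <- union(rec$kinases, ed$kinase[i])
        rec$w <- max(rec$w, ed$weight[i])
        assign(k, rec, envir = best)
      }
    }
  }
  keep <- vapply(chains, function(ch) {
    ed <- ch$edges
    for (i in seq_len(nrow(ed))) {
      k <- paste(ed$substrate[i], ed$site[i], sep = "@")
      rec <- get(k, envir = best)
      # only a genuine parallel delivery (>= 2 distinct kinases) competes
      if (length(rec$kinases) >= 2 && ed$weight[i] < rec$w) return(FALSE)
    }
    TRUE
  }, logical(1))
  kept <- chains[keep]
  ord <- order(vapply(kept, function(ch) ch$edges$kinase[1], ""),
               vapply(kept, function(ch) ch$key, ""), method = "radix")
  kept[ord]
}

#' Select chains by depth and effect size
#'
#' Keeps chains with strictly more than `min_intermediates` internal nodes
#' in which every edge carries a fold change — measured, or imputed via the
#' single-path rule — and every per-edge |CFC| exceeds `min_cfc` percent
#' (or their mean exceeds it, with `cfc_mode = "mean"`). A chain containing
#' an edge with no fold change at all has no reportable value for that
#' phosphorylation event and is never selected. Output is sorted by chain
#' score (the minimum edge weight) descending.
#'
#' @param chains List of `phospho_chain`s.
#' @param min_intermediates Exclusive bound on internal node count
#'   (default 2, i.e. chains need at least 3 intermediates).
#' @param min_cfc Exclusive bound (percent) on per-edge magnitude (default 5).
#' @param cfc_mode `"all"` or `"mean"`.
#' @return Filtered list sorted by score descending.
#' @export
select_chains <- function(chains, min_intermediates = 2, min_cfc = 5,
                          cfc_mode = c("all", "mean")) {
  cfc_mode <- match.arg(cfc_mode)
  keep <- vapply(chains, function(ch) {
    if (!(ch$n_intermediates > min_intermediates)) return(FALSE)
    if (anyNA(ch$per_edge_cfc)) return(FALSE)
    vals <- abs(ch$per_edge_cfc)
    if (cfc_mode == "all") all(vals > min_cfc) else mean(vals) > min_cfc
  }, logical(1))
  kept <- chains[keep]
  ord <- order(-vapply(kept, function(ch) ch$score, 0),
               vapply(kept, function(ch) ch$key, ""), method = "radix")
  kept[ord]
}

#' Full per-direction inference run
#'
#' Composes, for each direction: single-path imputation, random walks,
#' permutation-null enrichment, the enrichment threshold
#' (`enrichment >= hi` or `<= lo`), parallel-phosphorylation resolution, and
#' depth/effect-size selection. A *hit* is a measured phosphosite appearing
#' in at least one selected chain.
#'
#' @param up_network,down_network Direction subnetworks from [split_signed()].
#' @param config A [walk_config()].
#' @return List of class `infer_result` with `up_chains`, `down_chains`,
#'   `hits` (data frame `target`, `site`, `direction`, `cfc_percent`),
#'   `estimates` (per-direction `walk_estimate`s) and `config`.
#' @export
infer_direction_run <- function(up_network, down_network, config = walk_config()) {
  run_one <- function(network, direction) {
    if (nrow(network$edges) == 0) {
      return(list(chains = list(), estimate = NULL))
    }
    network <- impute_network(network, condition = "experimental",
                              seed = derive_seed(config$seed,
                                                 paste0("impute-", direction)),
                              fixed = config$impute == "fixed")
    est <- null_expectation(network,
                            n_walks = config$n_walks,
                            n_permutations = config$n_permutations,
                            seed = derive_seed(config$seed,
                                               paste0("walk-", direction)),
                            null_walks = config$null_walks,
                            epsilon = config$epsilon,
                            max_length = config$max_length)
    # effect-size band plus a binomial evidence gate (BH-adjusted): ratio
    # excursions of chains visited a handful of times are Poisson noise, not
    # over-/under-representation
    obs_count <- round(est$chains$observed * config$n_walks)
    p_hi <- stats::pbinom(obs_count - 1, config$n_walks, est$chains$expected,
                          lower.tail = FALSE)
    p_lo <- stats::pbinom(obs_count, config$n_walks, est$chains$expected)
    p_two <- pmin(1, 2 * pmin(p_hi, p_lo))
    q <- stats::p.adjust(p_two, method = "BH")
    keep <- (est$chains$enrichment >= config$enrichment_hi |
               est$chains$enrichment <= config$enrichment_lo) &
      q <= config$alpha
    est$chains$p_value <- p_two
    est$chains$q_value <- q
    est_kept <- est
    est_kept$chains <- est$chains[keep, , drop = FALSE]
    chains <- chains_from_estimate(est_kept, max_length = config$max_length)
    chains <- resolve_parallel(chains)
    chains <- select_chains(chains,
                            min_intermediates = config$min_intermediates,
                            min_cfc = config$min_cfc,
                            cfc_mode = config$cfc_mode)
    list(chains = chains, estimate = est)
  }
  up <- run_one(up_network, "up")
  down <- run_one(down_network, "down")
  hits <- lead_table(c(up$chains, down$chains))
  names(hits)[names(hits) == "n_chains"] <- "n_chains"
  structure(list(up_chains = up$chains, down_chains = down$chains,
                 hits = hits,
                 estimates = list(up = up$estimate, down = down$estimate),
                 config = config),
            class = "infer_result")
}

#' @export
print.infer_result <- function(x, ...) {
  cat(sprintf("<infer_result> %d up chains, %d down chains, %d hits\n",
              length(x$up_chains), length(x$down_chains), nrow(x$hits)))
  invisible(x)
}

#' Tabulate chains
#'
#' One row per chain: root, ordered node-site path, direction, per-edge CFC,
#' score, enrichment and termination reason.
#'
#' @param chains List of `phospho_chain`s.
#' @return A data frame.
#' @export
chains_to_df <- function(chains) {
  if (length(chains) == 0) {
    return(data.frame(root = character(), path = character(),
                      direction = character(), n_intermediates = integer(),
                      per_edge_cfc = character(), imputed = character(),
                      score = numeric(), observed = numeric(),
                      expected = numeric(), enrichment = numeric(),
                      termination_reason = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(chains, function(ch) {
    ed <- ch$edges
    data.frame(
      root = ed$kinase[1],
      path = paste0(ed$kinase[1],
                    paste0(ifelse(ed$effect == "inhibition", "-|", "->"),
                           ed$substrate, "@", ed$site, collapse = "")),
      direction = ch$direction,
      n_intermediates = ch$n_intermediates,
      per_edge_cfc = paste(sprintf("%.4g", ch$per_edge_cfc), collapse = ";"),
      imputed = paste(as.integer(ch$imputed), collapse = ";"),
      score = ch$score,
      observed = ch$observed,
      expected = ch$expected,
      enrichment = ch$enrichment,
      termination_reason = ch$termination_reason,
      stringsAsFactors = FALSE)
  }))
}

#' Write chains to TSV or JSON
#'
#' TSV carries the tabular view from [chains_to_df()]; JSON adds full
#' provenance (per-edge records, imputation flags, seeds).
#'
#' @param chains List of `phospho_chain`s.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param config Optional [walk_config()] recorded in the JSON provenance.
#' @export
write_chains <- function(chains, path, format = c("tsv", "json"),
                         config = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(chains_to_df(chains), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(
      config = if (!is.null(config)) unclass(config) else NULL,
      chains = lapply(chains, function(ch) {
        list(key = ch$key, direction = ch$direction,
             edges = ch$edges[c("kinase", "substrate", "site", "effect",
                                "cfc", "weight", "imputed")],
             n_intermediates = ch$n_intermediates,
             termination_reason = ch$termination_reason,
             score = ch$score, observed = ch$observed,
             expected = ch$expected, enrichment = ch$enrichment)
      }))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  }
  invisible(NULL)
}
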