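# Synthetic benchmark: random kinase-substrate networks with planted signed
# cascades, simulated noisy treated-vs-control antibody array tables in the
# array_io schema, and recovery scoring of the full pipeline against the
# planted truth.

#' Generate a random kinase-substrate relation table
#'
#' Random directed acyclic graph over synthetic gene symbols (`G001`, ...):
#' nodes get a topological order and each forward pair carries an edge
#' independently with probability `2 * mean_out_degree / (n_nodes - 1)`, so
#' the expected edge count is `n_nodes * mean_out_degree`. Each edge gets a
#' random phosphosite label on its substrate and is inhibitory independently
#' with probability `inhibition_fraction`. At least one root is guaranteed
#' by construction (the first node in the order never receives an edge); if
#' the draw yields no edge at all, the single edge `G001 -> G002` is added
#' so the result is a usable network.
#'
#' @param n_nodes Number of proteins (>= 2).
#' @param mean_out_degree Expected outgoing edges per node.
#' @param inhibition_fraction Probability that an edge is inhibitory.
#' @param seed Integer seed.
#' @return A `ks_relations` data frame.
#' @export
generate_network <- function(n_nodes, mean_out_degree = 2,
                             inhibition_fraction = 0.2, seed = 1) {
  if (n_nodes < 2) stop("parameter error: n_nodes must be >= 2", call. = FALSE)
  p <- 2 * mean_out_degree / (n_nodes - 1)
  if (p > 1) {
    stop("parameter error: mean_out_degree too large for n_nodes ",
         "(no DAG with that density)", call. = FALSE)
  }
  stopifnot(inhibition_fraction >= 0, inhibition_fraction <= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  syms <- sprintf("G%03d", seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  take <- stats::runif(nrow(pairs)) < p
  from <- pairs[take, 1]
  to <- pairs[take, 2]
  if (length(from) == 0) {
    from <- 1L
    to <- 2L
  }
  n_e <- length(from)
  res <- sample(c("S", "T", "Y"), n_e, replace = TRUE)
  pos <- sample.int(999, n_e, replace = TRUE)
  effect <- ifelse(stats::runif(n_e) < inhibition_fraction,
                   "inhibition", "activation")
  rel <- data.frame(kinase = syms[from], substrate = syms[to],
                    site = paste0(res, pos), effect = effect,
                    stringsAsFactors = FALSE)
  # drop the rare duplicate (kinase, substrate, site) triple
  rel <- rel[!duplicated(paste(rel$kinase, rel$substrate, rel$site)), ,
             drop = FALSE]
  as_ks_relations(rel, origin = "generated network")
}

#' Plant a signed cascade on a network
#'
#' Selects a root-anchored simple path of the requested edge length whose
#' non-terminal edges are all activating (so the path is a valid,
#' fully-traversable phosphorylation chain) and marks its substrate sites as
#' carrying the signed effect: `+effect_pct` for direction `"up"`,
#' `-effect_pct` for `"down"`.
#'
#' @param relations A `ks_relations` table.
#' @param length Number of edges in the cascade.
#' @param direction `"up"` or `"down"`.
#' @param effect_pct Positive percent change planted on each site.
#' @param seed Integer seed (path choice among candidates is seeded).
#' @return Data frame of the planted edges with columns `kinase`,
#'   `substrate`, `site`, `effect`, `cfc_true`, `direction`.
#' @export
plant_cascade <- function(relations, length, direction = c("up", "down"),
                          effect_pct = 30, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(effect_pct > 0, length >= 1)
  net <- build_network(relations)
  roots <- find_roots(net)
  if (base::length(roots) == 0) {
    stop("planting error: network has no root", call. = FALSE)
  }
  edges <- net$edges
  out_by_node <- split(seq_len(nrow(edges)), edges$kinase)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  found <- NULL
  dfs <- function(node, path, visited) {
    if (!is.null(found)) return(invisible())
    if (base::length(path) == length) {
      found <<- path
      return(invisible())
    }
    cand <- out_by_node[[node]]
    if (is.null(cand)) return(invisible())
    # interior edges must be activating; the terminal edge may be anything
    last_step <- base::length(path) == length - 1L
    if (!last_step) cand <- cand[edges$effect[cand] == "activation"]
    cand <- cand[!(edges$substrate[cand] %in% visited)]
    if (base::length(cand) == 0) return(invisible())
    for (e in cand[sample.int(base::length(cand))]) {
      dfs(edges$substrate[e], c(path, e), c(visited, edges$substrate[e]))
      if (!is.null(found)) return(invisible())
    }
  }
  for (r in roots[sample.int(base::length(roots))]) {
    dfs(r, integer(0), r)
    if (!is.null(found)) break
  }
  if (is.null(found)) {
    stop("planting error: no root-anchored path of length ", length,
         " exists", call. = FALSE)
  }
  planted <- edges[found, c("kinase", "substrate", "site", "effect")]
  planted$cfc_true <- if (direction == "up") effect_pct else -effect_pct
  planted$direction <- direction
  rownames(planted) <- NULL
  planted
}

#' Synthetic benchmark scenario
#'
#' Bundles the generator parameters, the generated relation network and the
#' planted truth. The defaults emulate a single KAM-style screen: a
#' 100-protein network with mean out-degree 2 and 20% inhibitory edges, one
#' planted 6-edge up-regulated cascade at +30% CFC, probe baselines of 5,000
#' fluorescence units with a lognormal per-probe factor (geometric SD 1.5),
#' 5% multiplicative signal noise and reported errors at 10% of signal.
#' Planting is rejection-sampled: if the drawn network admits no
#' root-anchored path of the requested length, a fresh network is drawn from
#' a derived seed (up to `max_tries`).
#'
#' @param n_nodes,mean_out_degree,inhibition_fraction Network shape, see
#'   [generate_network()].
#' @param planted_cascades List of cascade descriptors, each a list with
#'   `length`, `direction`, `effect_pct`. Use `list()` for a null scenario.
#' @param baseline_signal Mean control fluorescence (units); must exceed the
#'   array's low-signal threshold.
#' @param noise_sd_fraction Multiplicative Gaussian signal noise SD as a
#'   fraction of signal, applied to both channels.
#' @param error_sd_fraction Reported per-probe error SD as a fraction of
#'   signal.
#' @param n_replicates Number of simulated comparison tables.
#' @param seed Integer seed; all stages derive their streams from it.
#' @param max_tries Network redraws allowed while planting.
#' @return An object of class `synthetic_scenario` with elements `relations`
#'   (the network) and `truth` (planted edges, possibly empty).
#' @export
synthetic_scenario <- function(n_nodes = 100, mean_out_degree = 2,
                               inhibition_fraction = 0.2,
                               planted_cascades = list(
                                 list(length = 6, direction = "up",
                                      effect_pct = 30)),
                               baseline_signal = 5000,
                               noise_sd_fraction = 0.05,
                               error_sd_fraction = 0.1,
                               n_replicates = 1,
                               seed = 1,
                               max_tries = 50) {
  stopifnot(baseline_signal > 0, noise_sd_fraction >= 0,
            error_sd_fraction >= 0, n_replicates >= 1)
  relations <- NULL
  truth <- NULL
  for (attempt in seq_len(max_tries)) {
    net_seed <- derive_seed(seed, paste0("network-", attempt))
    rel <- generate_network(n_nodes, mean_out_degree, inhibition_fraction,
                            seed = net_seed)
    tr <- list()
    ok <- TRUE
    for (i in seq_along(planted_cascades)) {
      pc <- planted_cascades[[i]]
      res <- tryCatch(
        plant_cascade(rel, length = pc$length, direction = pc$direction,
                      effect_pct = pc$effect_pct,
                      seed = derive_seed(seed, paste0("plant-", attempt, "-", i))),
        error = function(e) e)
      if (inherits(res, "error")) {
        ok <- FALSE
        break
      }
      res$cascade <- i
      tr[[i]] <- res
    }
    if (ok) {
      relations <- rel
      truth <- if (length(tr) > 0) do.call(rbind, tr) else
        data.frame(kinase = character(), substrate = character(),
                   site = character(), effect = character(),
                   cfc_true = numeric(), direction = character(),
                   cascade = integer(), stringsAsFactors = FALSE)
      break
    }
  }
  if (is.null(relations)) {
    stop("planting error: no network admitted the requested cascade(s) in ",
         max_tries, " tries", call. = FALSE)
  }
  structure(list(n_nodes = n_nodes, mean_out_degree = mean_out_degree,
                 inhibition_fraction = inhibition_fraction,
                 planted_cascades = planted_cascades,
                 baseline_signal = baseline_signal,
                 noise_sd_fraction = noise_sd_fraction,
                 error_sd_fraction = error_sd_fraction,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 relations = relations, truth = truth),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_scenario> %d nodes, %d relations, ",
                     "%d planted cascade(s), noise %g%%, seed %d\n"),
              x$n_nodes, nrow(x$relations), length(x$planted_cascades),
              100 * x$noise_sd_fraction, x$seed))
  invisible(x)
}

#' Simulate antibody array comparison tables
#'
#' One phosphosite probe per distinct `(substrate, site)` of the scenario's
#' network plus one pan (expression) probe per node. Control signals are
#' `baseline_signal` times a lognormal per-probe factor (geometric SD 1.5);
#' treated signals are `control * (1 + cfc_true/100)` with `cfc_true` the
#' planted effect on planted sites and 0 elsewhere. Both channels then
#' receive multiplicative Gaussian noise (`noise_sd_fraction`) and reported
#' errors are drawn as half-normal with SD `error_sd_fraction * signal`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param spec An [array_spec()]; only its identity is recorded.
#' @return List with `tables` (a list of `n_replicates` probe tables in the
#'   array_io schema, treated and control channels paired per row) and
#'   `truth` (the planted edge table).
#' @export
simulate_arrays <- function(scenario, spec = array_spec("KAM-1325")) {
  rel <- scenario$relations
  sites <- unique(data.frame(target = rel$substrate, site = rel$site,
                             stringsAsFactors = FALSE))
  sites <- sites[order(sites$target, sites$site, method = "radix"), ,
                 drop = FALSE]
  nodes <- sort(unique(c(rel$kinase, rel$substrate)), method = "radix")
  probes <- rbind(
    data.frame(target = sites$target, site = sites$site,
               stringsAsFactors = FALSE),
    data.frame(target = nodes, site = "pan", stringsAsFactors = FALSE))
  probes$probe_id <- sprintf("P%04d", seq_len(nrow(probes)))

  truth <- scenario$truth
  tkey <- paste(truth$substrate, truth$site, sep = "@")
  pkey <- paste(probes$target, probes$site, sep = "@")
  cfc_true <- numeric(nrow(probes))
  m <- match(pkey, tkey)
  cfc_true[!is.na(m)] <- truth$cfc_true[m[!is.na(m)]]

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(scenario$seed, "arrays"))
  n <- nrow(probes)
  # per-probe baseline affinity factor, shared across replicates
  factor0 <- stats::rlnorm(n, meanlog = 0, sdlog = log(1.5))
  tables <- vector("list", scenario$n_replicates)
  for (r in seq_len(scenario$n_replicates)) {
    control <- scenario$baseline_signal * factor0
    treated <- control * (1 + cfc_true / 100)
    if (scenario$noise_sd_fraction > 0) {
      control <- control * (1 + stats::rnorm(n, 0, scenario$noise_sd_fraction))
      treated <- treated * (1 + stats::rnorm(n, 0, scenario$noise_sd_fraction))
    }
    control <- pmax(control, 0)
    treated <- pmax(treated, 0)
    terr <- abs(stats::rnorm(n, 0, scenario$error_sd_fraction * treated))
    cerr <- abs(stats::rnorm(n, 0, scenario$error_sd_fraction * control))
    df <- data.frame(probe_id = probes$probe_id, target = probes$target,
                     site = probes$site,
                     treated_signal = treated, treated_error = terr,
                     control_signal = control, control_error = cerr,
                     stringsAsFactors = FALSE)
    tables[[r]] <- as_probe_table(df, spec = spec, origin = "simulated array")
  }
  list(tables = tables, truth = truth)
}

#' Score planted-cascade recovery
#'
#' Compares the edges of the selected chains with the planted cascade edges
#' and the hit list with the planted sites.
#'
#' @param result An `infer_result` from [infer_direction_run()], or a plain
#'   list of selected `phospho_chain`s.
#' @param truth Planted edge table (from the scenario or
#'   [simulate_arrays()]).
#' @return List with `edge_precision`, `edge_recall`, `site_hit_recall`
#'   (all in \[0, 1\]; precision and recall are 1 by convention when both
#'   edge sets are empty) and `cfc_estimate` (mean measured |CFC| over
#'   correctly recovered edges, `NA` when none).
#' @export
recovery_metrics <- function(result, truth) {
  chains <- if (inherits(result, "infer_result")) {
    c(result$up_chains, result$down_chains)
  } else result
  sel_edges <- unique(unlist(lapply(chains, function(ch)
    paste(ch$edges$kinase, ch$edges$substrate, ch$edges$site, sep = "\r"))))
  planted <- unique(paste(truth$kinase, truth$substrate, truth$site,
                          sep = "\r"))
  tp <- intersect(sel_edges, planted)
  precision <- if (length(sel_edges) == 0) {
    if (length(planted) == 0) 1 else 0
  } else length(tp) / length(sel_edges)
  recall <- if (length(planted) == 0) 1 else length(tp) / length(planted)

  hit_sites <- if (inherits(result, "infer_result")) {
    unique(paste(result$hits$target, result$hits$site, sep = "@"))
  } else {
    unique(unlist(lapply(chains, function(ch) {
      meas <- !is.na(ch$edges$cfc) & !ch$edges$imputed
      paste(ch$edges$substrate[meas], ch$edges$site[meas], sep = "@")
    })))
  }
  planted_sites <- unique(paste(truth$substrate, truth$site, sep = "@"))
  site_recall <- if (length(planted_sites) == 0) 1 else
    length(intersect(hit_sites, planted_sites)) / length(planted_sites)

  cfc_vals <- unlist(lapply(chains, function(ch) {
    k <- paste(ch$edges$kinase, ch$edges$substrate, ch$edges$site, sep = "\r")
    keep <- k %in% planted & !is.na(ch$edges$cfc) & !ch$edges$imputed
    abs(ch$edges$cfc[keep])
  }))
  list(edge_precision = precision, edge_recall = recall,
       site_hit_recall = site_recall,
       cfc_estimate = if (length(cfc_vals) > 0) mean(cfc_vals) else NA_real_)
}

#' Run the full pipeline on a synthetic scenario
#'
#' Simulate arrays, preprocess, map onto the scenario network, infer chains
#' in both directions, and score recovery against the planted truth.
#'
#' @param scenario A [synthetic_scenario()].
#' @param spec An [array_spec()].
#' @param config A [walk_config()]; its `seed` defaults to the scenario
#'   seed so one scenario seed reproduces the whole run.
#' @param preprocess_config Options forwarded to [preprocess_pipeline()].
#' @return List with `result` (an `infer_result`), `metrics`
#'   (from [recovery_metrics()]), `report` (the `filter_report`) and
#'   `simulated` (tables + truth).
#' @export
run_scenario <- function(scenario, spec = array_spec("KAM-1325"),
                         config = NULL, preprocess_config = list()) {
  if (is.null(config)) {
    config <- walk_config(seed = derive_seed(scenario$seed, "infer"))
  }
  sim <- simulate_arrays(scenario, spec)
  pre <- preprocess_pipeline(sim$tables, spec, preprocess_config)
  net <- build_network(scenario$relations)
  net <- attach_measurements(net, pre$measurements)
  parts <- split_signed(net)
  result <- infer_direction_run(parts$up, parts$down, config)
  metrics <- recovery_metrics(result, sim$truth)
  list(result = result, metrics = metrics, report = pre$report,
       simulated = sim)
}
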