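# Shared test constructors: quick relation tables, measured networks and
# hand-built chains.

rel_df <- function(...) {
  # rel_df("A -> B @S1", "B -| C @S2") : "->" activation, "-|" inhibition,
  # "-?" unknown
  rows <- lapply(list(...), function(s) {
    m <- regmatches(s, regexec("^(\\w+) *(->|-\\||-\\?) *(\\w+) *@(\\w+)$", s))[[1]]
    stopifnot(length(m) == 5)
    effect <- c("->" = "activation", "-|" = "inhibition",
                "-?" = "unknown")[[m[3]]]
    data.frame(kinase = m[2], substrate = m[4], site = m[5], effect = effect,
               stringsAsFactors = FALSE)
  })
  as_ks_relations(do.call(rbind, rows))
}

# Build a measured network: cfc is a named vector "substrate@site" -> percent
measured_network <- function(relations, cfc = c()) {
  net <- build_network(relations)
  if (length(cfc) > 0) {
    key <- paste(net$edges$substrate, net$edges$site, sep = "@")
    idx <- match(key, names(cfc))
    hit <- !is.na(idx)
    net$edges$cfc[hit] <- unname(cfc[idx[hit]])
    net$edges$weight[hit] <- abs(net$edges$cfc[hit])
  }
  net
}

# Hand-built phospho_chain from an ordered edge data frame
mk_chain <- function(edges, direction = "up",
                     termination_reason = "sink") {
  if (is.null(edges$cfc)) edges$cfc <- NA_real_
  if (is.null(edges$weight)) {
    edges$weight <- ifelse(is.na(edges$cfc), 0, abs(edges$cfc))
  }
  if (is.null(edges$imputed)) edges$imputed <- FALSE
  rownames(edges) <- NULL
  structure(list(
    key = paste(seq_len(nrow(edges)), collapse = "-"),
    edges = edges,
    direction = direction,
    per_edge_cfc = edges$cfc,
    imputed = edges$imputed,
    n_intermediates = nrow(edges) - 1L,
    termination_reason = termination_reason,
    score = min(edges$weight),
    observed = NA_real_, expected = NA_real_, enrichment = NA_real_
  ), class = "phospho_chain")
}

chain_edge <- function(kinase, substrate, site, effect = "activation",
                       cfc = NA_real_, imputed = FALSE) {
  data.frame(kinase = kinase, substrate = substrate, site = site,
             effect = effect, cfc = cfc,
             weight = ifelse(is.na(cfc), 0, abs(cfc)),
             imputed = imputed, stringsAsFactors = FALSE)
}

# Probe table data frame shortcut
probe_df <- function(probe_id, target, site, t, terr, c, cerr) {
  data.frame(probe_id = probe_id, target = target, site = site,
             treated_signal = t, treated_error = terr,
             control_signal = c, control_error = cerr,
             stringsAsFactors = FALSE)
}

# Total-variation distance between an exact chain distribution and a walk
# estimate
tv_distance <- function(exact, estimate) {
  p <- stats::setNames(exact$prob, exact$key)
  q <- stats::setNames(estimate$chains$observed, estimate$chains$key)
  keys <- union(names(p), names(q))
  pv <- ifelse(is.na(p[keys]), 0, p[keys])
  qv <- ifelse(is.na(q[keys]), 0, q[keys])
  sum(abs(pv - qv)) / 2
}

# Random measured network for oracle-equivalence properties
random_measured_network <- function(seed, max_nodes = 12) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  mod <- min(2.2, stats::runif(1, 0.8, (n - 1) / 2))
  rel <- generate_network(n_nodes = n, mean_out_degree = mod,
                          inhibition_fraction = 0.3, seed = seed)
  net <- build_network(rel)
  ne <- nrow(net$edges)
  meas <- stats::runif(ne) < 0.7
  net$edges$cfc[meas] <- round(stats::runif(sum(meas), -40, 40), 1)
  net$edges$weight <- ifelse(is.na(net$edges$cfc), 0, abs(net$edges$cfc))
  net
}
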