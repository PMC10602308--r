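# Walk termination, imputation, exact enumeration, random walks, the
# permutation null, parallel resolution and chain selection.

test_that("termination rules: inhibition stops, exhausted nodes are sinks", {
  net <- measured_network(rel_df("PDK1 -> AKT @S473", "AKT -| BAD @S75",
                                 "AKT -> EZR @T567"))
  inhib_chain <- mk_chain(rbind(chain_edge("PDK1", "AKT", "S473"),
                                chain_edge("AKT", "BAD", "S75", "inhibition")))
  expect_equal(check_termination(inhib_chain, net), "inhibition")
  sink_chain <- mk_chain(rbind(chain_edge("PDK1", "AKT", "S473"),
                               chain_edge("AKT", "EZR", "T567")))
  expect_equal(check_termination(sink_chain, net), "sink")
  open_chain <- mk_chain(chain_edge("PDK1", "AKT", "S473"))
  expect_equal(check_termination(open_chain, net), "continue")
  # an edge already traversed does not count as an available path
  loop_net <- measured_network(rel_df("A -> B @S1", "B -> A @S2"))
  loop_chain <- mk_chain(rbind(chain_edge("A", "B", "S1"),
                               chain_edge("B", "A", "S2")))
  expect_equal(check_termination(loop_chain, loop_net), "sink")
  expect_error(check_termination(mk_chain(chain_edge("A", "B", "S1"))$edges[0, ],
                                 net), "nonempty")
})

test_that("single-path imputation: control fixed at 20, experimental seeded in [0, 20]", {
  net <- measured_network(rel_df("A -> B @S1", "B -> C @S2"),
                          cfc = c("S1" = 0)) # nothing measured
  expect_identical(impute_single_path("A", net, "control"), 20)
  v1 <- impute_single_path("A", net, "experimental", rng_seed = 99)
  v2 <- impute_single_path("A", net, "experimental", rng_seed = 99)
  expect_identical(v1, v2)
  expect_true(v1 >= 0 && v1 <= 20)
  expect_identical(impute_single_path("A", net, "experimental", fixed = TRUE),
                   10)
  branching <- measured_network(rel_df("A -> B @S1", "A -> C @S2"))
  expect_error(impute_single_path("A", branching), "not applicable")
  measured <- measured_network(rel_df("A -> B @S1"), cfc = c("B@S1" = 12))
  expect_error(impute_single_path("A", measured), "measured change")
})

test_that("exact enumeration matches hand-computed distributions", {
  # A -> B, then B -> C (activation) vs B -| D (inhibition), equal weights
  net <- measured_network(rel_df("A -> B @S1", "B -> C @S2", "B -| D @S3"))
  en <- enumerate_chains(net)
  expect_equal(nrow(en), 2)
  expect_equal(en$prob, c(0.5, 0.5))
  expect_equal(sum(en$prob), 1)

  single <- measured_network(rel_df("A -> B @S1"))
  en1 <- enumerate_chains(single)
  expect_equal(en1$prob, 1)

  cycle <- measured_network(rel_df("A -> B @S1", "B -> A @S2"))
  expect_error(enumerate_chains(cycle), "rootless")

  # weighted branch: weights 30 and 10, epsilon 1 -> 31/42 vs 11/42
  wnet <- measured_network(rel_df("A -> B @S1", "A -> C @S2"),
                           cfc = c("B@S1" = 30, "C@S2" = -10))
  enw <- enumerate_chains(wnet, epsilon = 1)
  expect_equal(sort(enw$prob), sort(c(31, 11) / 42))
})

test_that("random walks converge to the exact distribution and are seeded", {
  net <- measured_network(rel_df("A -> B @S1", "B -> C @S2", "B -| D @S3"))
  rw <- random_walk(net, 1e5, seed = 7)
  expect_equal(sum(rw$chains$observed), 1)
  expect_true(all(abs(rw$chains$observed - 0.5) < 0.01))
  single <- measured_network(rel_df("A -> B @S1"))
  expect_equal(random_walk(single, 100, seed = 1)$chains$observed, 1)
  rw2 <- random_walk(net, 1e5, seed = 7)
  expect_identical(rw$chains, rw2$chains)
  expect_error(random_walk(net, 0, seed = 1), "n_walks")
  cycle <- measured_network(rel_df("A -> B @S1", "B -> A @S2"))
  expect_error(random_walk(cycle, 10, seed = 1), "rootless")
})

test_that("walk frequencies match enumeration on random seeded networks", {
  worst <- 0
  for (s in 1:40) {
    net <- random_measured_network(s)
    tv <- tv_distance(enumerate_chains(net),
                      random_walk(net, 2e4, seed = s + 10000))
    worst <- max(worst, tv)
  }
  expect_lt(worst, 0.03) # binomial error bound at 2e4 walks
})

test_that("emitted chains never continue past an inhibitory edge", {
  for (s in 1:15) {
    net <- random_measured_network(s + 200)
    est <- random_walk(net, 5000, seed = s)
    chains <- chains_from_estimate(est)
    for (ch in chains) {
      inhib_pos <- which(ch$edges$effect == "inhibition")
      if (length(inhib_pos) > 0) {
        expect_equal(inhib_pos, nrow(ch$edges)) # only ever terminal
        expect_equal(ch$termination_reason, "inhibition")
      } else {
        expect_true(ch$termination_reason %in% c("sink", "max_length"))
      }
    }
  }
})

test_that("max_length caps walks and is labelled as the termination reason", {
  net <- measured_network(rel_df("A -> B @S1", "B -> C @S2", "C -> D @S3"))
  est <- random_walk(net, 100, seed = 1, max_length = 2)
  chains <- chains_from_estimate(est, max_length = 2)
  expect_equal(length(chains), 1)
  expect_equal(nrow(chains[[1]]$edges), 2)
  expect_equal(chains[[1]]$termination_reason, "max_length")
})

test_that("permutation null: flat weights give enrichment near 1", {
  net <- measured_network(
    rel_df("A -> B @S1", "A -> C @S2", "B -> D @S3", "C -> D @S4"),
    cfc = c("B@S1" = 10, "C@S2" = 10, "D@S3" = 10, "D@S4" = 10))
  est <- null_expectation(net, n_walks = 2e4, n_permutations = 30, seed = 3)
  expect_true(all(abs(est$chains$enrichment - 1) < 0.15))
  expect_error(null_expectation(net, 100, 0), "n_permutations")
})

test_that("permutation null: a heavy branch is enriched, the light depleted", {
  net <- measured_network(rel_df("A -> B @S1", "A -> C @S2"),
                          cfc = c("B@S1" = 100, "C@S2" = 10))
  est <- null_expectation(net, n_walks = 2e4, n_permutations = 50, seed = 5)
  heavy <- est$chains$enrichment[grepl("^1$", est$chains$key)]
  light <- est$chains$enrichment[grepl("^2$", est$chains$key)]
  expect_gt(heavy, 1.2)
  expect_lt(light, 0.8)
  est2 <- null_expectation(net, n_walks = 2e4, n_permutations = 50, seed = 5)
  expect_identical(est$chains, est2$chains)
})

test_that("parallel phosphorylation keeps the greater-magnitude delivery", {
  weak <- mk_chain(rbind(chain_edge("R1", "M", "S5", cfc = 20),
                         chain_edge("M", "JUN", "S73", cfc = 10)))
  strong <- mk_chain(rbind(chain_edge("R2", "N", "S6", cfc = 20),
                           chain_edge("N", "JUN", "S73", cfc = 25)))
  kept <- resolve_parallel(list(weak, strong))
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$edges$kinase[1], "R2")

  # different sites on the same substrate never compete
  pdk1 <- mk_chain(chain_edge("PDK1", "AKT", "S473", cfc = 25))
  src <- mk_chain(chain_edge("SRC", "AKT", "Y326", cfc = 10))
  expect_equal(length(resolve_parallel(list(pdk1, src))), 2)

  # ties keep all, ordered by first kinase
  t1 <- mk_chain(chain_edge("ZK", "JUN", "S73", cfc = 25))
  t2 <- mk_chain(chain_edge("AK", "JUN", "S73", cfc = 25))
  kept2 <- resolve_parallel(list(t1, t2))
  expect_equal(vapply(kept2, function(ch) ch$edges$kinase[1], ""),
               c("AK", "ZK"))
})

test_that("selection enforces depth and the per-edge CFC bound", {
  deep_edges <- rbind(chain_edge("A", "B", "S1", cfc = 6),
                      chain_edge("B", "C", "S2", cfc = 6),
                      chain_edge("C", "D", "S3", cfc = 6),
                      chain_edge("D", "E", "S4", cfc = 6))
  deep <- mk_chain(deep_edges) # 3 intermediates
  shallow <- mk_chain(deep_edges[1:3, ]) # 2 intermediates
  expect_equal(length(select_chains(list(deep, shallow))), 1)
  expect_equal(select_chains(list(deep, shallow))[[1]]$n_intermediates, 3L)

  weak_edges <- deep_edges
  weak_edges$cfc[2] <- 4
  weak_edges$weight[2] <- 4
  expect_equal(length(select_chains(list(mk_chain(weak_edges)))), 0)

  # an edge with no measured or imputed fold change blocks selection
  gap_edges <- deep_edges
  gap_edges$cfc[3] <- NA
  expect_equal(length(select_chains(list(mk_chain(gap_edges)))), 0)

  # the bound is exclusive
  at_bound <- deep_edges
  at_bound$cfc[] <- 5
  expect_equal(length(select_chains(list(mk_chain(at_bound)))), 0)

  # mean mode applies the bound to the average magnitude
  mixed <- deep_edges
  mixed$cfc <- c(4, 6, 6, 6)
  expect_equal(length(select_chains(list(mk_chain(mixed)), cfc_mode = "mean")),
               1)
})

test_that("raising the CFC bound never grows the selected set", {
  set.seed(1)
  chains <- lapply(1:30, function(i) {
    n <- sample(3:6, 1)
    ed <- do.call(rbind, lapply(seq_len(n), function(j)
      chain_edge(paste0("N", j), paste0("N", j + 1), paste0("S", j),
                 cfc = round(runif(1, 0, 30), 1))))
    mk_chain(ed)
  })
  sizes <- vapply(seq(0, 25, by = 5), function(thr)
    length(select_chains(chains, min_intermediates = 2, min_cfc = thr)),
    integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("full direction runs are reproducible and respect empty inputs", {
  net <- measured_network(
    rel_df("A -> B @S1", "B -> C @S2", "C -> D @S3", "D -> E @S4",
           "B -| F @S5"),
    cfc = c("B@S1" = 30, "C@S2" = 28, "D@S3" = 26, "E@S4" = 24, "F@S5" = 22))
  parts <- split_signed(net)
  cfg <- walk_config(n_walks = 5000, n_permutations = 50, null_walks = 1000,
                     seed = 4)
  r1 <- infer_direction_run(parts$up, parts$down, cfg)
  r2 <- infer_direction_run(parts$up, parts$down, cfg)
  expect_identical(chains_to_df(r1$up_chains), chains_to_df(r2$up_chains))
  expect_identical(r1$hits, r2$hits)
  expect_equal(length(r1$down_chains), 0) # all-positive network
  empty <- split_signed(measured_network(rel_df("A -> B @S1")))
  r0 <- infer_direction_run(empty$down, empty$down, cfg)
  expect_equal(length(r0$up_chains) + length(r0$down_chains), 0)
  expect_equal(nrow(r0$hits), 0)
})

test_that("chain tables and JSON exports carry provenance", {
  ch <- mk_chain(rbind(chain_edge("A", "B", "S1", cfc = 10),
                       chain_edge("B", "C", "S2", cfc = 8, imputed = TRUE)))
  df <- chains_to_df(list(ch))
  expect_equal(df$root, "A")
  expect_match(df$path, "A->B@S1->C@S2")
  expect_equal(df$imputed, "0;1")
  path <- withr::local_tempfile(fileext = ".json")
  write_chains(list(ch), path, "json", config = walk_config(seed = 3))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$config$seed, 3)
  expect_equal(back$chains$edges$kinase[[1]], c("A", "B"))
  expect_equal(back$chains$edges$imputed[[1]], c(FALSE, TRUE))
})
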