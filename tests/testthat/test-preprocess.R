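# The three quality filters and the fold-change computations.

test_that("percent change from control follows its definition", {
  expect_equal(compute_cfc(1500, 1000), 50)
  expect_equal(compute_cfc(1000, 1000), 0)
  expect_equal(compute_cfc(800, 1000), -20)
  expect_equal(compute_cfc(c(1500, 800), c(1000, 1000)), c(50, -20))
  expect_error(compute_cfc(1500, 0), "undefined CFC")
})

test_that("log2 fold change follows its definition", {
  expect_equal(compute_log2fc(2000, 1000), 1)
  expect_equal(compute_log2fc(1000, 1000), 0)
  expect_equal(compute_log2fc(500, 1000), -1)
  expect_error(compute_log2fc(0, 1000), "undefined")
})

test_that("low-signal filter removes on strictly-below with channel minimum", {
  spec1325 <- array_spec("KAM-1325")
  spec2000 <- array_spec("KAM-2000")
  tab <- as_probe_table(probe_df(
    c("a", "b", "c"), c("X", "Y", "Z"), c("S1", "S2", "S3"),
    t = c(999, 1500, 1000), terr = 0,
    c = c(1500, 999, 1000), cerr = 0))
  r <- filter_low_signal(tab, spec1325)
  expect_equal(r$removed, c("a", "b")) # either channel below disqualifies
  expect_equal(r$kept$probe_id, "c")   # equality retains

  tab2 <- as_probe_table(probe_df("d", "W", "S4", 500, 0, 500, 0))
  expect_equal(filter_low_signal(tab2, spec2000)$removed, character(0))

  empty <- tab[0, , drop = FALSE]
  r0 <- filter_low_signal(empty, spec1325)
  expect_equal(nrow(r0$kept), 0)
  expect_equal(r0$removed, character(0))
})

test_that("relative-error filter compares summed error to signal change", {
  tab <- as_probe_table(probe_df(
    c("a", "b", "c"), c("X", "Y", "Z"), c("S1", "S2", "S3"),
    t = c(1200, 1200, 1000), terr = c(300, 0, 50),
    c = c(1000, 1000, 1000), cerr = c(0, 0, 50)))
  r <- filter_relative_error(tab, 1.0)
  # a: ratio 300/200 = 1.5 removed; b: 0 retained; c: delta 0, error > 0
  expect_equal(r$removed, c("a", "c"))
  expect_equal(r$kept$probe_id, "b")
  # boundary: ratio exactly 1 retains
  tab_b <- as_probe_table(probe_df("d", "W", "S4", 1100, 50, 1000, 50))
  expect_equal(filter_relative_error(tab_b, 1.0)$removed, character(0))
})

test_that("total-error blacklist compares summed errors across conditions", {
  t1 <- as_probe_table(probe_df("p", "X", "S1", 1500, 120, 1200, 100))
  expect_equal(filter_total_error(list(t1)), "p")
  t2 <- as_probe_table(probe_df("p", "X", "S1", 1500, 100, 1200, 100))
  expect_equal(filter_total_error(list(t2)), character(0)) # strict inequality
  t3 <- as_probe_table(probe_df("p", "X", "S1", 1500, 0, 1200, 0))
  expect_equal(filter_total_error(list(t3)), character(0))
  # sums across replicate tables
  r1 <- as_probe_table(probe_df("p", "X", "S1", 1500, 60, 1200, 100))
  r2 <- as_probe_table(probe_df("p", "X", "S1", 1500, 70, 1200, 20))
  expect_equal(filter_total_error(list(r1, r2)), "p") # 130 > 120
  # probe present in one condition only
  q1 <- as_probe_table(probe_df("q", "Y", "S2", 1500, 10, 1200, 10))
  expect_error(filter_total_error(list(r1), list(q1)), "one condition only")
})

test_that("pipeline on the bundled 12-probe toy matches the hand oracle", {
  tabs <- toy12_probe_tables()
  res <- preprocess_pipeline(tabs, array_spec("KAM-1325"))
  rep <- res$report
  # hand computation: low-signal removes P02 (treated 999), P03 (control
  # 999), P10 (treated 800); relative error removes P05 (300/200 = 1.5) and
  # P08 (delta 0, error 100); total error across the two replicates removes
  # P09 (40+100 = 140 > 30+20 = 50); all other treated sums equal control
  # sums and are retained.
  expect_equal(rep$n_input, 12)
  expect_equal(rep$n_low_signal_removed, 3)
  expect_equal(rep$n_relative_error_removed, 2)
  expect_equal(rep$n_total_error_removed, 1)
  expect_equal(rep$n_retained, 6)
  expect_setequal(rep$removed_probe_ids$low_signal, c("P02", "P03", "P10"))
  expect_setequal(rep$removed_probe_ids$relative_error, c("P05", "P08"))
  expect_equal(rep$removed_probe_ids$total_error, "P09")
  expect_setequal(res$measurements$probe_id,
                  c("P01", "P04", "P06", "P07", "P11", "P12"))
  expect_equal(res$measurements$cfc_percent[res$measurements$probe_id == "P01"],
               100)
})

test_that("filtering conserves counts, is idempotent, and keeps sign parity", {
  tabs <- toy12_probe_tables()
  res <- preprocess_pipeline(tabs, array_spec("KAM-1325"))
  rep <- res$report
  expect_equal(rep$n_input,
               rep$n_retained + rep$n_low_signal_removed +
                 rep$n_relative_error_removed + rep$n_total_error_removed)
  # second application removes nothing further
  res2 <- preprocess_pipeline(res$measurements, array_spec("KAM-1325"))
  expect_equal(res2$report$n_retained, res2$report$n_input)
  expect_equal(res2$measurements$cfc_percent, res$measurements$cfc_percent)
  # sign(cfc) == sign(log2fc) for every retained probe
  expect_equal(sign(res$measurements$cfc_percent),
               sign(res$measurements$log2fc))
})

test_that("clean tables pass the pipeline untouched", {
  tab <- as_probe_table(probe_df(
    sprintf("p%d", 1:4), sprintf("G%d", 1:4), c("S1", "S2", "S3", "pan"),
    t = c(2000, 1500, 1200, 1800), terr = 0,
    c = c(1000, 1200, 1500, 1800), cerr = 0))
  res <- preprocess_pipeline(tab, array_spec("KAM-1325"))
  expect_equal(res$report$n_retained, 4)
  expect_equal(res$measurements$cfc_percent, c(100, 25, -20, 0))
})

test_that("filter reports serialize to JSON and text", {
  res <- preprocess_pipeline(toy12_probe_tables(), array_spec("KAM-1325"))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_filter_report(res$report, jpath, "json")
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$n_retained, 6)
  tpath <- withr::local_tempfile(fileext = ".txt")
  write_filter_report(res$report, tpath, "text")
  expect_match(paste(readLines(tpath), collapse = "\n"), "retained")
})
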