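# Probe tables, relation tables and lead tables: parsing, validation,
# round-trips.

test_that("probe tables read back in file order with validated fields", {
  df <- probe_df(c("a", "b", "c"), c("akt1", "TP53", "SRC"),
                 c("S473", "pan", "Y419"),
                 c(1500, 2000, 1200), c(10, 20, 30),
                 c(1000, 1800, 1100), c(5, 15, 25))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  tab <- read_probe_table(path, spec = array_spec("KAM-1325"))
  expect_s3_class(tab, "probe_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$probe_id, c("a", "b", "c"))
  expect_equal(tab$target, c("AKT1", "TP53", "SRC")) # upper-cased
  expect_equal(tab$treated_signal, c(1500, 2000, 1200))
  expect_null(tab$cfc_percent) # derived fields absent before preprocessing
})

test_that("probe table validation rejects bad sites, negatives, duplicates", {
  base <- probe_df("p1", "AKT", "S473", 1500, 10, 1000, 10)
  bad_site <- base
  bad_site$site <- "X99"
  expect_error(as_probe_table(bad_site), "invalid site 'X99'")
  expect_error(as_probe_table(transform(base, site = "pan5")), "invalid site")
  neg <- base
  neg$treated_signal <- -5
  expect_error(as_probe_table(neg), "negative treated_signal at row 1")
  dup <- rbind(base, base)
  expect_error(as_probe_table(dup), "duplicate probe_id 'p1'")
  empty_target <- base
  empty_target$target <- ""
  expect_error(as_probe_table(empty_target), "empty target")
})

test_that("missing probe-table columns are named in the error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- probe_df("p1", "AKT", "S473", 1500, 10, 1000, 10)
  df$control_error <- NULL
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_probe_table(path), "control_error")
  expect_error(read_probe_table(tempfile()), "not found")
})

test_that("write-then-read round-trips a generated 20-probe table", {
  set.seed(42)
  n <- 20
  df <- probe_df(sprintf("p%02d", 1:n), sprintf("G%02d", 1:n),
                 paste0(sample(c("S", "T", "Y"), n, TRUE),
                        sample(1:999, n)),
                 round(runif(n, 600, 4000), 3), round(runif(n, 0, 100), 3),
                 round(runif(n, 600, 4000), 3), round(runif(n, 0, 100), 3))
  tab <- as_probe_table(df)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(tab, path)
  back <- read_probe_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  # comma-separated variant via sep flag
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_probe_table(tab, path2, sep = ",")
  expect_equal(as.data.frame(read_probe_table(path2, sep = ",")),
               as.data.frame(tab))
})

test_that("relation tables parse effects, reject duplicates and bad tokens", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kinase\tsubstrate\tsite\teffect",
               "PDK1\tAKT\tS473\tactivation",
               "AKT\tBAD\tS75\tinhibition",
               "RAF1\tMAP2K1\tS218\tunknown"), path)
  rel <- read_ks_relations(path)
  expect_equal(nrow(rel), 3)
  expect_equal(rel$effect, c("activation", "inhibition", "unknown"))
  expect_equal(rel$kinase[1], "PDK1")
  expect_equal(rel$site[2], "S75")

  writeLines(c("kinase\tsubstrate\tsite\teffect",
               "PDK1\tAKT\tS473\tup"), path)
  expect_error(read_ks_relations(path), "unknown effect 'up'")

  writeLines(c("kinase\tsubstrate\tsite\teffect",
               "PDK1\tAKT\tS473\tactivation",
               "PDK1\tAKT\tS473\tinhibition"), path)
  expect_error(read_ks_relations(path), "duplicate relation")

  writeLines("kinase\tsubstrate\tsite\teffect", path)
  expect_equal(nrow(read_ks_relations(path)), 0)
})

test_that("SIF-like three-column relation input is accepted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\tinteraction\ttarget",
               "PDK1\tactivation\tAKT@S473",
               "AKT\tinhibition\tBAD@S75"), path)
  rel <- read_ks_relations(path)
  expect_equal(rel$substrate, c("AKT", "BAD"))
  expect_equal(rel$site, c("S473", "S75"))
  writeLines(c("source\tinteraction\ttarget",
               "PDK1\tactivation\tAKT"), path)
  expect_error(read_ks_relations(path), "substrate@site")
})

test_that("alias tables remap gene symbols on read", {
  aliases <- data.frame(alias = c("BCL2", "P70S6K"),
                        symbol = c("BAD", "RPS6KB1"))
  df <- data.frame(kinase = "AKT", substrate = "bcl2", site = "S75",
                   effect = "inhibition")
  rel <- as_ks_relations(df, aliases = aliases)
  expect_equal(rel$substrate, "BAD")
  tab <- as_probe_table(probe_df("p", "p70s6k", "T252", 1500, 1, 1000, 1),
                        aliases = aliases)
  expect_equal(tab$target, "RPS6KB1")
})

test_that("lead tables deduplicate measured sites and count chain membership", {
  ch1 <- mk_chain(rbind(chain_edge("PDK1", "AKT", "S473", cfc = 25),
                        chain_edge("AKT", "EZR", "T567", cfc = 22)))
  ch2 <- mk_chain(rbind(chain_edge("MAPK14", "AKT", "S473", cfc = 25),
                        chain_edge("AKT", "BAD", "S75", "inhibition",
                                   cfc = 30)),
                  termination_reason = "inhibition")
  leads <- lead_table(list(ch1, ch2))
  akt <- leads[leads$target == "AKT" & leads$site == "S473", ]
  expect_equal(nrow(akt), 1)
  expect_equal(akt$n_chains, 2L)
  expect_equal(akt$cfc_percent, 25)
  # sorted by target then site
  expect_equal(leads$target, sort(leads$target))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_lead_table(list(), path)
  lines <- readLines(path)
  expect_equal(length(lines), 1) # header only
  expect_match(lines, "target\tsite\tdirection")

  # imputed and unmeasured edges are not leads
  ch3 <- mk_chain(rbind(chain_edge("A", "B", "S1", cfc = 10, imputed = TRUE),
                        chain_edge("B", "C", "S2")))
  expect_equal(nrow(lead_table(list(ch3))), 0)
})
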