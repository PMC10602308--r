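# Bundled fixtures.
#
# fig2_*: a small regression network of kinase-substrate relations around the
# AKT (cell growth/survival) and CDK1 (cell cycle) signalling arms, together
# with a synthetic probe table whose signs reproduce the reported qualitative
# directions (AKT arm up-regulated, CDK1 arm down-regulated). The relation
# list is a hand-made transcription of published pathway structure at
# per-site resolution; the fluorescence values are synthetic and chosen only
# for their signs and rough magnitudes.
#
# toy12_*: a 12-probe array pair (two replicate comparison tables) whose
# signals are chosen so that each preprocessing filter removes at least one
# probe; the expected filter report is hand-computed in the test suite.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "phosphowalk", mustWork = FALSE)
  if (!nzchar(p)) {
    # during development (package loaded from source tree)
    p <- file.path("inst", "extdata", name)
  }
  p
}

#' Bundled regression-fixture relations (AKT / CDK1 arms)
#'
#' @return A `ks_relations` data frame with 16 per-site relations.
#' @export
fig2_relations <- function() {
  read_ks_relations(fixture_path("fig2_relations.tsv"))
}

#' Bundled regression-fixture probe table
#'
#' Synthetic signals, sign-consistent with the reported directions: the AKT
#' arm sites (AKT S473/Y326, BAD S75, EZR T567) are up-regulated and the
#' CDK1 arm sites (CDK1 T161/Y15, JUN S73, RPS6KB1 T252/S447, TP53 S37,
#' ESR1, IRS1) down-regulated.
#'
#' @return A `probe_table` with 13 phosphosite probes and one pan probe.
#' @export
fig2_probe_table <- function() {
  read_probe_table(fixture_path("fig2_probes.tsv"),
                   spec = array_spec("KAM-1325"))
}

#' Bundled 12-probe filter toy fixture
#'
#' @return A list of two replicate `probe_table`s.
#' @export
toy12_probe_tables <- function() {
  spec <- array_spec("KAM-1325")
  list(read_probe_table(fixture_path("toy12_probes_rep1.tsv"), spec = spec),
       read_probe_table(fixture_path("toy12_probes_rep2.tsv"), spec = spec))
}
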