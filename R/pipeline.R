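#' Run the differential-binding pipeline end to end
#'
#' Chains the standard analysis: per-replicate deduplication, RT-artifact
#' pentamer filtering, joint-peak definition on pooled conditions, and the
#' site-wise differential binding test.
#'
#' @param reads Read tibble with both conditions (see [read_bed6()]).
#' @param genes Gene-model tibble.
#' @param genome Genome as from [read_genome_fasta()].
#' @param cfg A [clip_config()].
#' @return A list: `reads` (cleaned), `artifact` (filter output), `jps`,
#'   `sites`.
#' @export
run_differential_binding <- function(reads, genes, genome,
                                     cfg = clip_config()) {
  dedup <- deduplicate_reads(reads)
  art <- filter_rt_artifacts(dedup, genome)
  jps <- define_joint_peaks(art$kept, genes, cfg)
  sites <- site_differential_test(jps, cfg)
  list(reads = art$kept, artifact = art, jps = jps, sites = sites)
}

#' Run the splicing analysis on a junction-count table
#'
#' @param junctions Long junction-count tibble with a `kind` column
#'   (`cassette` / `ale`).
#' @param cfg A [clip_config()].
#' @return Quantified events with `fdr` and `significant`.
#' @export
run_splicing_analysis <- function(junctions, cfg = clip_config()) {
  ev <- bind_rows(
    if (any(junctions$kind == "cassette")) {
      quantify_cassette(junctions[junctions$kind == "cassette", ], cfg)
    },
    if (any(junctions$kind == "ale")) {
      quantify_ale(junctions[junctions$kind == "ale", ], cfg)
    }
  )
  splicing_multiple_testing(ev, cfg)
}
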