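#' Relative peak heights of joint peaks
#'
#' The relative peak height (RPH) of a joint peak is 100 x (reads of a
#' condition in the JP) / (reads of that condition in all same-class intronic
#' or exonic JPs of the gene), so within each gene, region class and condition
#' the RPHs sum to 100. A zero denominator yields `NA` (the site is untested
#' rather than infinite).
#'
#' @param jps JP tibble from [define_joint_peaks()].
#' @return `jps` with `rph_mn` and `rph_wsc` columns added.
#' @export
relative_peak_heights <- function(jps) {
  jps |>
    mutate(rph_mn = ifelse(.data$M > 0, 100 * .data$m / .data$M, NA_real_),
           rph_wsc = ifelse(.data$N > 0, 100 * .data$n / .data$N, NA_real_))
}

#' Site-wise differential binding test on joint peaks
#'
#' For each joint peak, a two-sided Fisher's exact test on the 2x2 matrix
#' `rbind(c(m, M - m), c(n, N - n))` compares the share of MN reads in the JP
#' with the share of WSC reads, cancelling library-size differences. Coverage
#' is the smallest of the four cells; JPs with coverage below `coverage_min`
#' are untested. Benjamini-Hochberg correction is applied separately within
#' the intronic and exonic families, over coverage-passing JPs only. The fold
#' change is the ratio of relative peak heights (MN over WSC); a site is
#' called `over` when `fdr <= site_fdr` and `fold >= site_fold`, `under` when
#' `fdr <= site_fdr` and `fold <= 1/site_fold`.
#'
#' @param jps JP tibble from [define_joint_peaks()].
#' @param cfg A [clip_config()]; uses `coverage_min`, `site_fdr`, `site_fold`.
#' @return A tibble of class `clip_sites`: the JP columns plus `rph_mn`,
#'   `rph_wsc`, `fold_change`, `coverage`, `p_value`, `fdr`, `call`.
#' @export
site_differential_test <- function(jps, cfg = clip_config()) {
  res <- relative_peak_heights(jps) |>
    mutate(
      coverage = pmin(.data$m, .data$M - .data$m, .data$n, .data$N - .data$n),
      fold_change = .data$rph_mn / .data$rph_wsc,
      tested = .data$coverage >= cfg$coverage_min
    )
  res$p_value <- NA_real_
  idx <- which(res$tested)
  if (length(idx)) {
    res$p_value[idx] <- vapply(idx, function(i) {
      fisher_exact_two_sided(res$m[i], res$M[i] - res$m[i],
                             res$n[i], res$N[i] - res$n[i])
    }, numeric(1))
  }
  res <- res |>
    group_by(.data$region_class) |>
    mutate(fdr = bh_fdr(.data$p_value)) |>
    ungroup() |>
    mutate(
      call = case_when(
        !tested ~ "untested",
        fdr <= cfg$site_fdr & fold_change >= cfg$site_fold ~ "over",
        fdr <= cfg$site_fdr & fold_change <= 1 / cfg$site_fold ~ "under",
        TRUE ~ "unchanged"
      )
    ) |>
    select(-"tested")
  class(res) <- c("clip_sites", class(res))
  res
}

#' Gene-wise CLIP-read enrichment between conditions
#'
#' For each gene the MN and WSC reads within its peaks are summed and tested
#' against the null that the MN share equals the MN library fraction, using a
#' conditional exact binomial test: given `T = mn + wsc`,
#' `mn ~ Binomial(T, lib_mn / (lib_mn + lib_wsc))` under no enrichment. The
#' log2 fold change is depth-normalised with a 0.5 pseudo-count. BH-corrected
#' across genes; direction is `enriched`/`depleted` at `fdr <= gene_fdr`.
#'
#' @param gene_counts Tibble with `gene_id`, `mn_count`, `wsc_count`.
#' @param lib_mn,lib_wsc Condition library sizes (total mapped reads).
#' @param cfg A [clip_config()]; uses `gene_fdr`.
#' @return Tibble with `gene_id`, counts, `log_fold`, `p_value`, `fdr`,
#'   `direction`.
#' @export
genewise_enrichment <- function(gene_counts, lib_mn, lib_wsc,
                                cfg = clip_config()) {
  if (lib_mn <= 0 || lib_wsc <= 0) stop("library sizes must be positive")
  p0 <- lib_mn / (lib_mn + lib_wsc)
  res <- as_tibble(gene_counts)
  total <- res$mn_count + res$wsc_count
  res$log_fold <- log2(((res$mn_count + 0.5) / lib_mn) /
                         ((res$wsc_count + 0.5) / lib_wsc))
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    if (total[i] == 0) return(1)
    binom.test(res$mn_count[i], total[i], p0)$p.value
  }, numeric(1))
  res$fdr <- bh_fdr(res$p_value)
  res$direction <- case_when(
    res$fdr <= cfg$gene_fdr & res$log_fold > 0 ~ "enriched",
    res$fdr <= cfg$gene_fdr & res$log_fold < 0 ~ "depleted",
    TRUE ~ "ns"
  )
  class(res) <- c("clip_gene_enrichment", class(res))
  res
}
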