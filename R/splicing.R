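#' Quantify cassette-exon events from junction counts
#'
#' Per condition the two inclusion-junction counts are pooled across
#' replicates and averaged (`I = (sum(i1) + sum(i2)) / 2`, each included
#' transcript supports both junctions) and the skip junction summed
#' (`E = sum(e)`); the inclusion fraction is `psi = I / (I + E)` and
#' `dI = psi_MN - psi_WSC`. The p-value is a two-sided Fisher's exact test on
#' the pooled `rbind(c(round(I_MN), E_MN), c(round(I_WSC), E_WSC))` (averaged
#' inclusion counts rounded half-even to integers). Biological consistency
#' (`bc_consistent`) requires every per-replicate MN-vs-WSC psi difference to
#' share the sign of the pooled `dI`. An event is `expressed` when the pooled
#' junction coverage `I + E` is strictly over `expressed_junction_min` in both
#' conditions; unexpressed events carry `NA` statistics.
#'
#' @param counts Long junction-count tibble (see
#'   [simulate_junction_counts()]): `event_id`, `gene_id`, `condition`,
#'   `replicate`, `i1`, `i2`, `e`.
#' @param cfg A [clip_config()]; uses `expressed_junction_min`.
#' @return One row per event: psi per condition, `dI`, `p_value`,
#'   `expressed`, `bc_consistent`.
#' @export
quantify_cassette <- function(counts, cfg = clip_config()) {
  per_cond <- counts |>
    group_by(.data$event_id, .data$gene_id, .data$condition) |>
    summarise(I = (sum(.data$i1) + sum(.data$i2)) / 2, E = sum(.data$e),
              .groups = "drop")
  per_rep <- counts |>
    mutate(psi_rep = ifelse(.data$i1 + .data$i2 + 2 * .data$e > 0,
                            ((.data$i1 + .data$i2) / 2) /
                              ((.data$i1 + .data$i2) / 2 + .data$e),
                            NA_real_))
  quantify_two_group(per_cond, per_rep, kind = "cassette", cfg = cfg)
}

#' Quantify alternative last exon usage from junction counts
#'
#' Per condition the junction reads into the first ALE (`ale1`) and into the
#' competing last exon(s) (`ale2`) are pooled across replicates; usage
#' `psi = ale1 / (ale1 + ale2)`, `dI = psi_MN - psi_WSC`, with a pooled
#' two-sided Fisher's exact test. Expression and biological consistency are
#' defined as for cassette events.
#'
#' @param counts Long junction-count tibble with `ale1`, `ale2`.
#' @param cfg A [clip_config()].
#' @return One row per event, as for [quantify_cassette()].
#' @export
quantify_ale <- function(counts, cfg = clip_config()) {
  per_cond <- counts |>
    group_by(.data$event_id, .data$gene_id, .data$condition) |>
    summarise(I = sum(.data$ale1), E = sum(.data$ale2), .groups = "drop")
  per_rep <- counts |>
    mutate(psi_rep = ifelse(.data$ale1 + .data$ale2 > 0,
                            .data$ale1 / (.data$ale1 + .data$ale2),
                            NA_real_))
  quantify_two_group(per_cond, per_rep, kind = "ale", cfg = cfg)
}

quantify_two_group <- function(per_cond, per_rep, kind, cfg) {
  wide <- per_cond |>
    tidyr::pivot_wider(names_from = "condition", values_from = c("I", "E"))
  need <- c("I_MN", "E_MN", "I_WSC", "E_WSC")
  missing <- setdiff(need, names(wide))
  for (m in missing) wide[[m]] <- 0
  res <- wide |>
    mutate(
      psi_mn = ifelse(.data$I_MN + .data$E_MN > 0,
                      .data$I_MN / (.data$I_MN + .data$E_MN), NA_real_),
      psi_wsc = ifelse(.data$I_WSC + .data$E_WSC > 0,
                       .data$I_WSC / (.data$I_WSC + .data$E_WSC), NA_real_),
      dI = .data$psi_mn - .data$psi_wsc,
      expressed = (.data$I_MN + .data$E_MN > cfg$expressed_junction_min) &
        (.data$I_WSC + .data$E_WSC > cfg$expressed_junction_min),
      kind = kind
    )
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    if (!res$expressed[i] || is.na(res$dI[i])) return(NA_real_)
    fisher_exact_two_sided(round(res$I_MN[i]), round(res$E_MN[i]),
                           round(res$I_WSC[i]), round(res$E_WSC[i]))
  }, numeric(1))
  # per-replicate sign consistency: every MN replicate vs every WSC replicate
  pair_sign <- per_rep |>
    group_by(.data$event_id) |>
    summarise(signs = list({
      mnp <- .data$psi_rep[.data$condition == "MN"]
      wsp <- .data$psi_rep[.data$condition == "WSC"]
      as.vector(outer(mnp, wsp, `-`))
    }), .groups = "drop")
  res <- left_join(res, pair_sign, by = "event_id")
  res$bc_consistent <- vapply(seq_len(nrow(res)), function(i) {
    d <- res$dI[i]
    s <- res$signs[[i]]
    s <- s[!is.na(s)]
    if (is.na(d) || d == 0 || !length(s)) return(FALSE)
    all(sign(s) == sign(d))
  }, logical(1))
  res |>
    select("event_id", "gene_id", "kind", "psi_mn", "psi_wsc", "dI",
           "I_MN", "E_MN", "I_WSC", "E_WSC", "expressed", "bc_consistent",
           "p_value")
}

#' FDR correction and significance calls for splicing events
#'
#' BH correction is applied within each event kind over expressed events only
#' (unexpressed events keep `NA` fdr and are never called). A cassette event
#' is called significant at `fdr <= splicing_fdr` with biological
#' consistency; an ALE event additionally requires `|dI| >= ale_dI`.
#'
#' @param events Event tibble from [quantify_cassette()] / [quantify_ale()]
#'   (can be a mixture of kinds).
#' @param cfg A [clip_config()].
#' @return `events` with `fdr` and logical `significant` added.
#' @export
splicing_multiple_testing <- function(events, cfg = clip_config()) {
  events |>
    group_by(.data$kind) |>
    mutate(fdr = bh_fdr(ifelse(.data$expressed, .data$p_value, NA_real_))) |>
    ungroup() |>
    mutate(significant = case_when(
      !expressed | is.na(fdr) ~ FALSE,
      kind == "cassette" ~ fdr <= cfg$splicing_fdr & bc_consistent,
      kind == "ale" ~ fdr <= cfg$splicing_fdr & bc_consistent &
        abs(dI) >= cfg$ale_dI,
      TRUE ~ FALSE
    ))
}
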