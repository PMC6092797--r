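#' Predict splicing direction from differential binding position (RNA map)
#'
#' Binding within a 400-nt hotspot around an alternative exon predicts the
#' direction of its inclusion change: a site over-represented in MN upstream
#' of the exon predicts repression in MN (`dI < 0`), a downstream
#' over-represented site predicts activation (`dI > 0`); under-represented
#' sites flip the sign. A site inside the exon body is treated like upstream
#' binding (repression-direction), the dominant mode for exonic binding of
#' this factor family. Offsets are measured strand-aware from the site centre
#' to the nearest exon boundary (negative = upstream intron). When several
#' differential sites hit one exon's hotspot with conflicting signs the site
#' with the smallest FDR wins; exact ties yield no prediction.
#'
#' @param sites A `clip_sites` tibble from [site_differential_test()]
#'   restricted to called sites (`call` over/under); untested or unchanged
#'   sites yield no prediction.
#' @param events Event-location tibble: `event_id`, `gene_id`, `chrom`,
#'   `strand`, `exon_start`, `exon_end`.
#' @param cfg A [clip_config()]; uses `hotspot_nt`.
#' @return One row per event with at least one in-hotspot differential site:
#'   `event_id`, `site_id` (the winning JP), `offset`,
#'   `predicted_direction` (+1 or -1), `site_fdr`.
#' @export
predict_splicing_direction <- function(sites, events, cfg = clip_config()) {
  sites <- sites[sites$call %in% c("over", "under"), , drop = FALSE]
  rows <- vector("list", 0)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    cand <- sites[sites$gene_id == ev$gene_id, , drop = FALSE]
    if (nrow(cand) == 0) next
    if (any(cand$chrom != ev$chrom)) {
      cand <- cand[cand$chrom == ev$chrom, , drop = FALSE]
    }
    centre <- (cand$start + cand$end) %/% 2L
    off <- site_offset(centre, ev$exon_start, ev$exon_end, ev$strand)
    inside <- abs(off) <= cfg$hotspot_nt
    cand <- cand[inside, , drop = FALSE]
    off <- off[inside]
    if (nrow(cand) == 0) next
    # upstream or exonic binding gain represses; downstream gain activates
    dir_up <- ifelse(cand$call == "over", -1L, 1L)
    pred <- ifelse(off > 0, -dir_up, dir_up)
    best <- order(cand$fdr)[1]
    tie <- which(cand$fdr == cand$fdr[best])
    if (length(unique(pred[tie])) > 1) next
    rows[[length(rows) + 1L]] <- tibble(
      event_id = ev$event_id, site_id = cand$jp_id[best],
      offset = off[best], predicted_direction = pred[best],
      site_fdr = cand$fdr[best]
    )
  }
  bind_rows(rows)
}

# signed strand-aware offset of a position from an exon: negative upstream of
# the exon's 3' splice site, positive downstream of its 5' splice site, 0
# inside the exon body
site_offset <- function(pos, exon_start, exon_end, strand) {
  off <- ifelse(pos < exon_start, pos - exon_start,
                ifelse(pos >= exon_end, pos - exon_end + 1L, 0L))
  if (strand == "-") -off else off
}

#' Concordance between predicted and observed splicing direction
#'
#' Joins RNA-map predictions to quantified events; a prediction is evaluated
#' only when the event is significant (`fdr <= splicing_fdr`), and is
#' concordant when `sign(dI)` matches the predicted direction.
#'
#' @param predictions Output of [predict_splicing_direction()].
#' @param events Quantified events with `event_id`, `dI`, `fdr` (from
#'   [splicing_multiple_testing()]).
#' @param cfg A [clip_config()].
#' @return A one-row tibble: `n_predicted`, `n_concordant`, `fraction`
#'   (NA when nothing is evaluable).
#' @export
evaluate_concordance <- function(predictions, events, cfg = clip_config()) {
  j <- inner_join(predictions, events, by = "event_id") |>
    filter(!is.na(.data$fdr), .data$fdr <= cfg$splicing_fdr, .data$dI != 0)
  n_pred <- nrow(j)
  n_conc <- sum(sign(j$dI) == j$predicted_direction)
  tibble(n_predicted = n_pred, n_concordant = n_conc,
         fraction = if (n_pred > 0) n_conc / n_pred else NA_real_)
}

#' Hypergeometric overlap of two sets within a universe
#'
#' @param set_a,set_b Character vectors (subsets of `universe`), or integers
#'   giving `|A|`, `|B|` together with `overlap`.
#' @param universe Character vector, or integer `|universe|`.
#' @param overlap Only when sizes are given directly: `|A intersect B|`.
#' @return One-row tibble: `n_universe`, `n_a`, `n_b`, `overlap`, `expected`,
#'   `p_value` (upper tail).
#' @export
overlap_enrichment <- function(set_a, set_b, universe, overlap = NULL) {
  if (is.numeric(set_a) && length(set_a) == 1) {
    n_u <- universe; n_a <- set_a; n_b <- set_b; ov <- overlap
  } else {
    if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
      stop("sets must be subsets of the universe")
    }
    n_u <- length(unique(universe)); n_a <- length(unique(set_a))
    n_b <- length(unique(set_b)); ov <- length(intersect(set_a, set_b))
  }
  tibble(n_universe = n_u, n_a = n_a, n_b = n_b, overlap = ov,
         expected = n_a * n_b / n_u,
         p_value = hypergeom_upper_tail(n_u, n_b, n_a, ov))
}

#' Gene-set enrichment of a target list against a background
#'
#' Upper-tail hypergeometric test per gene set, BH-corrected across sets.
#' Sets with no member in the background are skipped with a warning.
#'
#' @param targets Character vector of target genes (subset of `background`).
#' @param background Character vector of background genes.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param fdr_threshold Significance threshold reported in the `significant`
#'   column (default 0.05).
#' @return Tibble: `set`, `k` (target hits), `n_targets`, `K` (background
#'   hits), `n_background`, `p_value`, `fdr`, `significant`.
#' @export
gene_set_enrichment <- function(targets, background, sets,
                                fdr_threshold = 0.05) {
  if (!length(background)) stop("empty background")
  if (!all(targets %in% background)) {
    stop("targets must be a subset of the background")
  }
  background <- unique(background)
  targets <- unique(targets)
  K <- vapply(sets, function(s) length(intersect(s, background)), integer(1))
  if (any(K == 0)) {
    warning("skipping ", sum(K == 0), " set(s) with no background member")
  }
  keep <- K > 0
  sets <- sets[keep]; K <- K[keep]
  k <- vapply(sets, function(s) length(intersect(s, targets)), integer(1))
  p <- vapply(seq_along(sets), function(i) {
    hypergeom_upper_tail(length(background), K[i], length(targets), k[i])
  }, numeric(1))
  tibble(set = names(sets), k = k, n_targets = length(targets), K = K,
         n_background = length(background), p_value = p, fdr = bh_fdr(p),
         significant = bh_fdr(p) < fdr_threshold) |>
    arrange(.data$p_value, .data$set)
}

#' Concordance of gene-wise binding direction with gene categories
#'
#' For each category of genes (e.g. anatomically restricted expression
#' groups), counts directional genes (gene-wise enrichment `fdr <= gene_fdr`)
#' that are enriched versus depleted, and tests the category's enriched
#' fraction against the global directional proportion with a 1-df chi-squared
#' goodness-of-fit test.
#'
#' @param gene_categories Tibble with `gene_id`, `category` (disjoint
#'   labels).
#' @param enrichment Output of [genewise_enrichment()].
#' @return Per-category tibble: `category`, `n_enriched`, `n_depleted`,
#'   `fraction_enriched`, `p_value` (NA for categories without directional
#'   genes).
#' @export
category_concordance <- function(gene_categories, enrichment) {
  dir_genes <- enrichment |>
    filter(.data$direction %in% c("enriched", "depleted"))
  global_prop <- mean(dir_genes$direction == "enriched")
  out <- gene_categories |>
    group_by(.data$category) |>
    summarise(
      n_enriched = sum(.data$gene_id %in%
                         dir_genes$gene_id[dir_genes$direction == "enriched"]),
      n_depleted = sum(.data$gene_id %in%
                         dir_genes$gene_id[dir_genes$direction == "depleted"]),
      .groups = "drop"
    )
  tot <- out$n_enriched + out$n_depleted
  out$fraction_enriched <- ifelse(tot > 0, out$n_enriched / tot, NA_real_)
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    if (tot[i] == 0 || is.nan(global_prop) ||
        global_prop <= 0 || global_prop >= 1) {
      return(NA_real_)
    }
    chi_squared_gof(c(out$n_enriched[i], out$n_depleted[i]), global_prop)
  }, numeric(1))
  out
}
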