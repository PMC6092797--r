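#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the site-wise differential binding result
#'
#' @param x A `clip_sites` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-site results (tested sites first).
#' @export
tidy.clip_sites <- function(x, ...) {
  as_tibble(x) |>
    arrange(.data$call == "untested", .data$fdr, .data$p_value)
}

#' One-row summary of the site-wise differential binding result
#'
#' @param x A `clip_sites` tibble.
#' @param ... Unused.
#' @return Tibble with JP counts, tested counts and calls per direction.
#' @export
glance.clip_sites <- function(x, ...) {
  tibble(
    n_jps = nrow(x),
    n_tested = sum(x$call != "untested"),
    n_over = sum(x$call == "over"),
    n_under = sum(x$call == "under"),
    median_coverage = stats::median(x$coverage[x$call != "untested"])
  )
}

#' One-row summary of gene-wise CLIP enrichment
#'
#' @param x A `clip_gene_enrichment` tibble.
#' @param ... Unused.
#' @return Tibble with gene counts per direction.
#' @export
glance.clip_gene_enrichment <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_enriched = sum(x$direction == "enriched"),
    n_depleted = sum(x$direction == "depleted")
  )
}
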