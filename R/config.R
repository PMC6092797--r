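#' Run configuration with the pipeline's default cutoffs
#'
#' Collects every named threshold used across the pipeline, with defaults set
#' to the values the analysis was designed around: per-gene peak significance
#' `peak_alpha = 0.01`; site-wise differential binding `site_fdr = 0.1` with
#' `site_fold = 2` and a minimum 2x2 coverage of `coverage_min = 10`; gene-wise
#' enrichment `gene_fdr = 0.01`; splicing `splicing_fdr = 0.1` with ALE calls
#' additionally requiring `|dI| >= ale_dI = 0.2`; junction coverage strictly
#' over `expressed_junction_min = 10` for an event to count as expressed; the
#' `hotspot_nt = 400` window of the RNA map; and `motif_halfwindow = 100` for
#' windowed tetramer enrichment. Replicate-group sizes default to 8 (MN) and
#' 4 (WSC) with joint-peak biological-complexity cutoffs of at least half of
#' either group.
#'
#' @param ... Named overrides of any default.
#' @param seed Integer seed recorded in the configuration.
#' @return A named list of class `clip_config`.
#' @export
clip_config <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    peak_alpha = 0.01,
    site_fdr = 0.1,
    site_fold = 2.0,
    coverage_min = 10,
    gene_fdr = 0.01,
    splicing_fdr = 0.1,
    ale_dI = 0.2,
    expressed_junction_min = 10,
    hotspot_nt = 400,
    motif_halfwindow = 100,
    n_replicates = c(MN = 8L, WSC = 4L),
    bc_min = c(MN = 4L, WSC = 2L)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown configuration fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  num <- vapply(
    cfg[c("peak_alpha", "site_fdr", "site_fold", "coverage_min", "gene_fdr",
          "splicing_fdr", "ale_dI", "expressed_junction_min", "hotspot_nt",
          "motif_halfwindow")],
    function(x) x[[1]], numeric(1)
  )
  if (any(num <= 0)) stop("all thresholds must be positive")
  structure(cfg, class = "clip_config")
}

#' Read or write a run configuration as YAML
#'
#' @param path File path.
#' @return `read_clip_config()` returns a `clip_config`;
#'   `write_clip_config()` returns `path` invisibly.
#' @export
read_clip_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$n_replicates <- if (!is.null(raw$n_replicates)) unlist(raw$n_replicates)
  raw$bc_min <- if (!is.null(raw$bc_min)) unlist(raw$bc_min)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(clip_config, c(raw[setdiff(names(raw), "seed")],
                         seed = raw$seed %||% 1L))
}

#' @rdname read_clip_config
#' @param config A `clip_config` object.
#' @export
write_clip_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
  }), path)
  invisible(path)
}
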