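#' Call CLIP peaks per gene against a uniform-coverage null
#'
#' The null for a gene with `R` reads of mean length `Lbar` over a
#' transcription unit of length `G` is per-base coverage ~ Poisson(R * Lbar /
#' G), i.e. reads falling uniformly at random over the unit. The significance
#' height `k*` is the smallest coverage whose Poisson upper tail, Bonferroni
#' adjusted over the `G` positions of the unit, is at most `alpha` (a
#' per-base correction; the coarser `G / Lbar` effective-window count
#' understates the chance that the maximum of a correlated clump exceeds the
#' threshold and is anti-conservative). Peaks are maximal runs of coverage
#' `>= k*`;
#' the per-peak p-value is the adjusted tail at the run's summit, and only
#' peaks with `p <= alpha` are returned.
#'
#' @param reads Read tibble (one condition or pooled; strand-matched reads
#'   within each gene's transcription unit are used).
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param alpha Per-gene significance level (default 0.01).
#' @param lib_size Library size used for reads-per-million normalised heights
#'   (defaults to `nrow(reads)`).
#' @return Peak tibble: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `summit_height`, `read_count`, `normalized_height`, `p_value`,
#'   `region_class`.
#' @export
call_peaks <- function(reads, genes, alpha = 0.01, lib_size = NULL) {
  lib_size <- lib_size %||% nrow(reads)
  out <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gr <- gene_reads(reads, genes[g, ])
    out[[g]] <- call_peaks_one(gr, genes[g, ], alpha, lib_size)
  }
  bind_rows(out)
}

gene_reads <- function(reads, gene) {
  reads[reads$chrom == gene$chrom & reads$strand == gene$strand &
          reads$end > gene$tu_start & reads$start < gene$tu_end, ,
        drop = FALSE]
}

call_peaks_one <- function(gr, gene, alpha, lib_size) {
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  summit_height = integer(), read_count = integer(),
                  normalized_height = double(), p_value = double(),
                  region_class = character())
  G <- gene$tu_end - gene$tu_start
  if (G <= 0) stop("empty transcription unit for gene ", gene$gene_id)
  if (nrow(gr) == 0) return(empty)
  lbar <- mean(gr$end - gr$start)
  lambda <- nrow(gr) * lbar / G
  ntests <- G # per-base Bonferroni: the G/mean-length clump heuristic proved anti-conservative
  # coverage over the unit via interval difference accumulation
  s <- pmax(gr$start, gene$tu_start) - gene$tu_start
  e <- pmin(gr$end, gene$tu_end) - gene$tu_start
  add_s <- tabulate(s + 1L, nbins = G + 1L)
  add_e <- tabulate(e + 1L, nbins = G + 1L)
  cov <- cumsum(add_s - add_e)[seq_len(G)]
  kmax <- max(cov)
  if (kmax < 1) return(empty)
  tails <- pmin(1, ntests * poisson_upper_tail(lambda, seq_len(kmax)))
  kstar <- which(tails <= alpha)[1]
  if (is.na(kstar)) return(empty)
  r <- rle(cov >= kstar)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(i) {
    ps <- gene$tu_start + starts[i] - 1L
    pe <- gene$tu_start + ends[i]
    summit <- max(cov[starts[i]:ends[i]])
    p <- tails[summit]
    if (p > alpha) return(NULL)
    rc <- sum(gr$start < pe & gr$end > ps)
    tibble(gene_id = gene$gene_id, chrom = gene$chrom,
           start = as.integer(ps), end = as.integer(pe),
           strand = gene$strand, summit_height = as.integer(summit),
           read_count = as.integer(rc),
           normalized_height = rc / lib_size * 1e6,
           p_value = p,
           region_class = classify_region((ps + pe) %/% 2L, gene))
  })
  bind_rows(rows)
}

# category of a position by midpoint: exon > intron > downstream
classify_region <- function(mid, gene) {
  ex <- gene$exons[[1]]
  if (nrow(ex) && any(mid >= ex$start & mid < ex$end)) return("exon")
  if (mid >= gene$start && mid < gene$end) return("intron")
  "downstream"
}

#' Biological complexity of peaks
#'
#' Number of distinct biological replicates contributing at least one
#' overlapping read to each peak.
#'
#' @param peaks Peak tibble.
#' @param reads Read tibble carrying `replicate` labels.
#' @return Integer vector, one value per peak.
#' @export
biological_complexity <- function(peaks, reads) {
  vapply(seq_len(nrow(peaks)), function(i) {
    hit <- reads$chrom == peaks$chrom[i] & reads$strand == peaks$strand[i] &
      reads$start < peaks$end[i] & reads$end > peaks$start[i]
    length(unique(reads$replicate[hit]))
  }, integer(1))
}

#' Define joint peaks over pooled conditions
#'
#' Runs the peak caller on reads pooled from both conditions, keeps joint
#' peaks (JPs) with reads from at least half of the biological replicates in
#' either group (MN BC >= 4/8 or WSC BC >= 2/4 under the defaults), and fills
#' the 2x2 counts for the site-wise test: `m`/`n` are the MN/WSC reads in the
#' JP and `M`/`N` the MN/WSC reads summed over all same-class (intronic or
#' exonic) JPs of the gene. JPs whose midpoint falls in the downstream
#' extension are not part of the intron/exon testing families and are
#' dropped.
#'
#' @param reads Pooled read tibble with both conditions.
#' @param genes Gene-model tibble.
#' @param cfg A [clip_config()]; uses `peak_alpha`, `n_replicates`, `bc_min`.
#' @return JP tibble: `jp_id`, `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `region_class`, `bc_mn`, `bc_wsc`, `m`, `n`, `M`, `N`.
#' @export
define_joint_peaks <- function(reads, genes, cfg = clip_config()) {
  for (cond in c("MN", "WSC")) {
    reps <- unique(reads$replicate[reads$condition == cond])
    if (length(reps) && max(reps) > cfg$n_replicates[[cond]]) {
      stop("replicate labels exceed configured replicate count for ", cond)
    }
  }
  peaks <- call_peaks(reads, genes, alpha = cfg$peak_alpha)
  if (nrow(peaks) == 0) {
    return(tibble(jp_id = character(), gene_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), region_class = character(),
                  bc_mn = integer(), bc_wsc = integer(), m = integer(),
                  n = integer(), M = integer(), N = integer()))
  }
  mn <- reads[reads$condition == "MN", , drop = FALSE]
  wsc <- reads[reads$condition == "WSC", , drop = FALSE]
  peaks$bc_mn <- biological_complexity(peaks, mn)
  peaks$bc_wsc <- biological_complexity(peaks, wsc)
  peaks <- peaks[peaks$bc_mn >= cfg$bc_min[["MN"]] |
                   peaks$bc_wsc >= cfg$bc_min[["WSC"]], , drop = FALSE]
  peaks <- peaks[peaks$region_class %in% c("exon", "intron"), , drop = FALSE]
  if (nrow(peaks) == 0) {
    return(define_joint_peaks(reads[0, ], genes, cfg))
  }
  peaks$m <- count_reads_in(peaks, mn)
  peaks$n <- count_reads_in(peaks, wsc)
  peaks |>
    group_by(.data$gene_id, .data$region_class) |>
    mutate(M = sum(.data$m), N = sum(.data$n)) |>
    ungroup() |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$gene_id) |>
    mutate(jp_id = sprintf("%s_jp%d", .data$gene_id, row_number())) |>
    ungroup() |>
    select("jp_id", "gene_id", "chrom", "start", "end", "strand",
           "region_class", "bc_mn", "bc_wsc", "m", "n", "M", "N")
}

count_reads_in <- function(peaks, reads) {
  vapply(seq_len(nrow(peaks)), function(i) {
    sum(reads$chrom == peaks$chrom[i] & reads$strand == peaks$strand[i] &
          reads$start < peaks$end[i] & reads$end > peaks$start[i])
  }, integer(1))
}

#' Randomly downsample reads without replacement
#'
#' Used to match the complexity of the deeper library before comparing
#' normalised peak heights between replicate groups.
#'
#' @param reads Read tibble.
#' @param target_count Number of reads to keep (`<= nrow(reads)`).
#' @param seed Optional seed for a reproducible sample.
#' @return The sampled tibble, original row order preserved.
#' @export
downsample_reads <- function(reads, target_count, seed = NULL) {
  if (target_count > nrow(reads)) stop("target_count exceeds read count")
  pick <- if (is.null(seed)) {
    sample.int(nrow(reads), target_count)
  } else {
    withr::with_seed(seed, sample.int(nrow(reads), target_count))
  }
  reads[sort(pick), , drop = FALSE]
}

#' Squared correlation of normalised peak heights between replicate groups
#'
#' Peaks are matched by identical intervals (inner join on chrom, start, end,
#' strand); the statistic is the squared Pearson correlation of
#' `log10(normalized_height + 0.5)` over matched peaks.
#'
#' @param peaks_a,peaks_b Peak tibbles with `normalized_height`.
#' @return R-squared (scalar).
#' @export
replicate_group_correlation <- function(peaks_a, peaks_b) {
  j <- inner_join(peaks_a, peaks_b,
                  by = c("chrom", "start", "end", "strand"),
                  suffix = c("_a", "_b"))
  if (nrow(j) < 3) stop("fewer than 3 matched peaks")
  cor(log10(j$normalized_height_a + 0.5),
      log10(j$normalized_height_b + 0.5))^2
}
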