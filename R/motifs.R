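#' Positional motif enrichment around peak centres
#'
#' For each offset `x` in `[-half_window, +half_window]` (transcript-strand
#' orientation, 0 = the floor midpoint of the peak), the observed frequency is
#' the fraction of peaks whose oriented sequence has a class-matching 4-mer
#' starting at `x`. The expectation comes from the i.i.d. mononucleotide
#' composition of the analysed sequence (or a supplied composition): for YCAY
#' `pY * pC * pA * pY` with `pY = pC + pT`; for YYYY `pY^4`; for U-rich
#' (two or more uridines, scanned as T) the binomial closed form
#' `1 - (1-pT)^4 - 4 pT (1-pT)^3`. Enrichment is observed/expected per offset.
#' Peaks whose window overruns a chromosome end are dropped and counted.
#'
#' @param peaks Peak tibble (needs `chrom`, `start`, `end`, `strand`).
#' @param genome Genome as from [read_genome_fasta()].
#' @param motif_class One of `"YCAY"`, `"YYYY"`, `"U-rich"`.
#' @param half_window Half-width of the profile in nt.
#' @param base_probs Optional composition (A, C, G, T) for the expectation;
#'   defaults to the composition of the scanned windows themselves.
#' @return A tibble of class `clip_motif_profile`: `offset`, `observed`,
#'   `expected`, `enrichment`, `n_peaks`; attribute `n_dropped`.
#' @export
positional_motif_enrichment <- function(peaks, genome,
                                        motif_class = c("YCAY", "YYYY",
                                                        "U-rich"),
                                        half_window = 500L,
                                        base_probs = NULL) {
  motif_class <- match.arg(motif_class)
  hw <- as.integer(half_window)
  win <- peak_windows(peaks, genome, hw + 3L)
  n <- nrow(win$peaks)
  if (n == 0) stop("no peaks with a full window")
  offsets <- -hw:hw
  hits <- matrix(FALSE, n, length(offsets))
  comp_counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_len(n)) {
    ch <- strsplit(win$seq[i], "", fixed = TRUE)[[1]]
    tb <- table(factor(ch, levels = c("A", "C", "G", "T")))
    comp_counts <- comp_counts + as.integer(tb)
    is_match <- motif_match_starts(ch, motif_class)
    # oriented centre sits at index hw + 4; a 4-mer at offset x starts at
    # index hw + 4 + x
    hits[i, ] <- is_match[hw + 4L + offsets]
  }
  observed <- colMeans(hits)
  if (is.null(base_probs)) {
    base_probs <- comp_counts / sum(comp_counts)
  }
  expected <- motif_expected_freq(base_probs, motif_class)
  if (expected <= 0) {
    stop("degenerate base composition: expected frequency of ", motif_class,
         " is zero")
  }
  out <- tibble(offset = offsets, observed = observed, expected = expected,
                enrichment = observed / expected, n_peaks = n)
  attr(out, "n_dropped") <- win$n_dropped
  attr(out, "motif_class") <- motif_class
  class(out) <- c("clip_motif_profile", class(out))
  out
}

# oriented windows of +/- half nt around each peak's floor midpoint; peaks
# too close to a chromosome edge are dropped
peak_windows <- function(peaks, genome, half) {
  centre <- (peaks$start + peaks$end) %/% 2L
  ws <- centre - half
  we <- centre + half + 1L
  len <- nchar(genome)[peaks$chrom]
  ok <- ws >= 0L & we <= len & peaks$chrom %in% names(genome)
  peaks <- peaks[ok, , drop = FALSE]
  s <- oriented_subseq(genome, peaks$chrom, ws[ok], we[ok], peaks$strand)
  list(peaks = peaks, seq = s, n_dropped = sum(!ok))
}

# logical vector over 4-mer start positions in a character vector
motif_match_starts <- function(ch, motif_class) {
  L <- length(ch)
  y <- ch == "C" | ch == "T"
  tt <- ch == "T"
  a <- ch == "A"
  cc <- ch == "C"
  i <- seq_len(L - 3L)
  switch(motif_class,
    "YCAY" = y[i] & cc[i + 1L] & a[i + 2L] & y[i + 3L],
    "YYYY" = y[i] & y[i + 1L] & y[i + 2L] & y[i + 3L],
    "U-rich" = (tt[i] + tt[i + 1L] + tt[i + 2L] + tt[i + 3L]) >= 2L
  )
}

motif_expected_freq <- function(base_probs, motif_class) {
  p <- base_probs / sum(base_probs)
  pY <- p[["C"]] + p[["T"]]
  switch(motif_class,
    "YCAY" = pY * p[["C"]] * p[["A"]] * pY,
    "YYYY" = pY^4,
    "U-rich" = 1 - (1 - p[["T"]])^4 - 4 * p[["T"]] * (1 - p[["T"]])^3
  )
}

#' Windowed tetramer enrichment of target versus background peaks
#'
#' Counts tetramer occurrences within `half_window` nt around the centre of
#' each target peak and compares them with the counts around background peaks
#' using an upper-tail hypergeometric test: the population is all 4-mer start
#' positions in the background windows, successes are occurrences of the
#' tetramer there, draws are the 4-mer starts in the target windows.
#' Overlapping windows double-count by design. BH correction across all 256
#' tetramers.
#'
#' @param target_peaks,background_peaks Peak tibbles; targets should be a
#'   subset of the background family.
#' @param genome Genome.
#' @param half_window Window half-width (default 100 nt).
#' @return Tibble: `tetramer`, `count_target`, `count_background`,
#'   `total_target`, `total_background`, `p_value`, `fdr`, ordered by p.
#' @export
tetramer_window_enrichment <- function(target_peaks, background_peaks, genome,
                                       half_window = 100L) {
  if (nrow(target_peaks) == 0) stop("empty target peak set")
  tet <- all_tetramers()
  cnt_t <- tetramer_counts(target_peaks, genome, half_window, tet)
  cnt_b <- tetramer_counts(background_peaks, genome, half_window, tet)
  tot_t <- sum(cnt_t)
  tot_b <- sum(cnt_b)
  p <- vapply(seq_along(tet), function(i) {
    obs <- min(cnt_t[i], cnt_b[i]) # guard: target should be within background
    hypergeom_upper_tail(tot_b, cnt_b[i], tot_t, obs)
  }, numeric(1))
  tibble(tetramer = tet, count_target = as.integer(cnt_t),
         count_background = as.integer(cnt_b),
         total_target = as.integer(tot_t),
         total_background = as.integer(tot_b),
         p_value = p, fdr = bh_fdr(p)) |>
    arrange(.data$p_value, .data$tetramer)
}

all_tetramers <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b, b)[, 4:1], 1, paste, collapse = "")
}

tetramer_counts <- function(peaks, genome, half, tet) {
  win <- peak_windows(peaks, genome, half)
  counts <- setNames(integer(length(tet)), tet)
  for (s in win$seq) {
    L <- nchar(s)
    if (L < 4) next
    fours <- substring(s, 1:(L - 3), 4:L)
    tb <- table(fours)
    keep <- intersect(names(tb), tet)
    counts[keep] <- counts[keep] + as.integer(tb[keep])
  }
  counts
}

#' Conservation-score profile around peak centres
#'
#' Per-offset mean of per-base conservation scores over peaks with data at
#' that offset, with normal-approximation 95% confidence bounds
#' (mean +/- 1.96 sd / sqrt(n)). Bases missing from the track are absent, not
#' zero; offsets with fewer than two covered peaks get no interval.
#'
#' @param peaks Peak tibble.
#' @param score_track BedGraph tibble from [read_bedgraph()].
#' @param genome Genome (for window bounds).
#' @param half_window Profile half-width in nt.
#' @return Tibble: `offset`, `mean_score`, `ci95_low`, `ci95_high`, `n`.
#' @export
conservation_profile <- function(peaks, score_track, genome,
                                 half_window = 100L) {
  hw <- as.integer(half_window)
  lookup <- lapply(split(score_track, score_track$chrom), function(tr) tr)
  centre <- (peaks$start + peaks$end) %/% 2L
  offsets <- -hw:hw
  acc_n <- acc_s <- acc_ss <- numeric(length(offsets))
  for (i in seq_len(nrow(peaks))) {
    tr <- lookup[[peaks$chrom[i]]]
    if (is.null(tr)) next
    pos <- centre[i] + (if (peaks$strand[i] == "+") offsets else -offsets)
    sc <- rep(NA_real_, length(pos))
    for (k in seq_len(nrow(tr))) {
      inside <- pos >= tr$start[k] & pos < tr$end[k]
      sc[inside] <- tr$score[k]
    }
    has <- !is.na(sc)
    acc_n <- acc_n + has
    acc_s <- acc_s + ifelse(has, sc, 0)
    acc_ss <- acc_ss + ifelse(has, sc^2, 0)
  }
  mean_score <- ifelse(acc_n > 0, acc_s / acc_n, NA_real_)
  var_hat <- ifelse(acc_n > 1,
                    pmax(0, (acc_ss - acc_n * mean_score^2) / (acc_n - 1)),
                    NA_real_)
  half_ci <- 1.96 * sqrt(var_hat / acc_n)
  out <- tibble(offset = offsets, mean_score = mean_score,
                ci95_low = mean_score - half_ci,
                ci95_high = mean_score + half_ci,
                n = as.integer(acc_n))
  class(out) <- c("clip_conservation_profile", class(out))
  out
}
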