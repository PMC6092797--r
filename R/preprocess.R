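#' Collapse duplicate CLIP reads
#'
#' Keeps at most one read per (chrom, start, end, strand) within each
#' condition/replicate, retaining the first occurrence. Identical intervals in
#' different replicates survive: biological complexity depends on
#' per-replicate provenance. Exact-position collapse stands in for
#' degenerate-barcode deduplication, which operates upstream of alignment.
#'
#' @param reads A read tibble (see [read_bed6()]).
#' @return The deduplicated tibble, input order preserved.
#' @export
deduplicate_reads <- function(reads) {
  reads |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand,
             .data$condition, .data$replicate, .keep_all = TRUE)
}

#' Remove reverse-transcription artifact reads by downstream pentamer
#'
#' RT can be mis-primed by GUGUC-like pentamers in the captured RNA, producing
#' reads whose 3' ends abut such pentamers. For every read the 5-mer starting
#' immediately after its 3' end (strand-aware) is extracted; all observed
#' pentamers are ranked by frequency across the dataset (both conditions
#' pooled), and reads are removed when their downstream pentamer is among the
#' `top_n` most frequent pentamers *and* within Hamming distance
#' `max_mismatch` of GTGTC. Reads with less than 5 nt of 3' flank cannot be
#' evaluated and are kept.
#'
#' The alternative reading of the rule ("the `top_n` most frequent of the
#' GTGTC-like pentamers", rather than "GTGTC-like members of the overall top
#' `top_n`") is available as `rule = "top_of_like"`.
#'
#' @param reads Read tibble.
#' @param genome Genome as from [read_genome_fasta()].
#' @param top_n Number of top-ranked pentamers considered.
#' @param max_mismatch Maximum Hamming distance to GTGTC.
#' @param rule `"within_top"` (default) or `"top_of_like"`.
#' @return A list with `kept`, `removed` (read tibbles), `pentamer_report`
#'   (tibble of pentamer, count, rank, distance_to_GTGTC, flagged) and
#'   `n_unevaluable` (reads with insufficient flank).
#' @export
filter_rt_artifacts <- function(reads, genome, top_n = 20L, max_mismatch = 1L,
                                rule = c("within_top", "top_of_like")) {
  rule <- match.arg(rule)
  if (nrow(reads) == 0) {
    return(list(kept = reads, removed = reads,
                pentamer_report = tibble(pentamer = character(),
                                         count = integer(), rank = integer(),
                                         distance_to_GTGTC = integer(),
                                         flagged = logical()),
                n_unevaluable = 0L))
  }
  if (any(!reads$chrom %in% names(genome))) {
    stop("read chromosome absent from genome")
  }
  chrom_len <- nchar(genome)[reads$chrom]
  plus <- reads$strand == "+"
  # pentamer immediately downstream of the 3' end on the read strand
  p_start <- ifelse(plus, reads$end, reads$start - 5L)
  evaluable <- p_start >= 0L & (p_start + 5L) <= chrom_len
  pent <- rep(NA_character_, nrow(reads))
  if (any(evaluable)) {
    raw <- genome_subseq(genome, reads$chrom[evaluable],
                         p_start[evaluable], p_start[evaluable] + 5L)
    neg <- !plus[evaluable]
    if (any(neg)) raw[neg] <- reverse_complement(raw[neg])
    pent[evaluable] <- unname(raw)
  }
  counts <- sort(table(pent[evaluable]), decreasing = TRUE)
  report <- tibble(
    pentamer = names(counts), count = as.integer(counts),
    rank = seq_along(counts),
    distance_to_GTGTC = hamming_to(names(counts), "GTGTC")
  )
  flagged_set <- if (rule == "within_top") {
    report$pentamer[report$rank <= top_n &
                      report$distance_to_GTGTC <= max_mismatch]
  } else {
    like <- report[report$distance_to_GTGTC <= max_mismatch, ]
    head(like$pentamer[order(like$rank)], top_n)
  }
  report$flagged <- report$pentamer %in% flagged_set
  drop <- !is.na(pent) & pent %in% flagged_set
  list(kept = reads[!drop, , drop = FALSE],
       removed = reads[drop, , drop = FALSE],
       pentamer_report = report,
       n_unevaluable = sum(!evaluable))
}

hamming_to <- function(x, ref) {
  refc <- strsplit(ref, "")[[1]]
  vapply(strsplit(x, ""), function(ch) {
    if (length(ch) != length(refc)) return(length(refc))
    sum(ch != refc)
  }, integer(1))
}

#' Genomic distribution of reads across annotation categories
#'
#' Assigns each read by its midpoint with priority exon > intron >
#' downstream-10kb; reads outside every transcription unit are reported as
#' `unassigned`.
#'
#' @param reads Read tibble (deduplicated).
#' @param genes Gene-model tibble.
#' @return Tibble with `category`, `n`, `fraction` (fractions sum to 1).
#' @export
genomic_distribution <- function(reads, genes) {
  mid <- (reads$start + reads$end) %/% 2L
  cat <- rep("unassigned", nrow(reads))
  for (g in seq_len(nrow(genes))) {
    on_chr <- reads$chrom == genes$chrom[g] & reads$strand == genes$strand[g]
    in_tu <- on_chr & mid >= genes$tu_start[g] & mid < genes$tu_end[g]
    if (!any(in_tu)) next
    in_gene <- in_tu & mid >= genes$start[g] & mid < genes$end[g]
    ex <- genes$exons[[g]]
    in_ex <- rep(FALSE, nrow(reads))
    for (k in seq_len(nrow(ex))) {
      in_ex <- in_ex | (in_gene & mid >= ex$start[k] & mid < ex$end[k])
    }
    cat[in_ex] <- "exon"
    cat[in_gene & !in_ex & cat != "exon"] <- "intron"
    cat[in_tu & !in_gene & cat == "unassigned"] <- "downstream"
  }
  tibble(category = cat) |>
    count(.data$category) |>
    mutate(fraction = .data$n / sum(.data$n))
}
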