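#' Read gene models from GTF
#'
#' Builds one transcription unit per `gene_id`: the gene span extended
#' `downstream` nucleotides past the 3' end (strand-aware) and clipped at the
#' chromosome bounds, mirroring the convention of treating a gene region plus
#' its downstream 10 kb as the unit over which CLIP reads are interpreted.
#' Exons are unioned across transcripts and sorted, so they are non-overlapping
#' within each gene.
#'
#' @param path GTF file with gene/transcript/exon features carrying `gene_id`.
#' @param chrom_lengths Named integer vector of chromosome lengths, or a
#'   genome as returned by [read_genome_fasta()] (lengths are taken from it).
#' @param downstream Nucleotides of downstream extension (default 10 kb).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (gene span), `tu_start`, `tu_end` (transcription unit) and
#'   an `exons` list-column of tibbles with `start`, `end`. All coordinates
#'   0-based half-open.
#' @export
read_gene_models <- function(path, chrom_lengths, downstream = 10000L) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  df$chrom <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$start0 <- df$start - 1L # GTF is 1-based closed
  df$end0 <- df$end
  build_gene_models(df, chrom_lengths, downstream)
}

build_gene_models <- function(df, chrom_lengths, downstream) {
  if (is.character(chrom_lengths)) chrom_lengths <- nchar(chrom_lengths)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("unknown strand in gene models: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  }
  genes <- df |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      start = min(.data$start0), end = max(.data$end0),
      exons = list({
        s0 <- .data$start0[.data$type == "exon"]
        e0 <- .data$end0[.data$type == "exon"]
        merge_intervals(tibble(start = s0, end = e0))
      }),
      .groups = "drop"
    )
  gene_feats <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gene_feats)) {
    for (i in seq_len(nrow(gene_feats))) {
      g <- gene_feats$gene_id[i]
      ex <- genes$exons[[match(g, genes$gene_id)]]
      if (nrow(ex) && (min(ex$start) < gene_feats$start0[i] ||
                       max(ex$end) > gene_feats$end0[i])) {
        stop("exon outside gene span for gene ", g)
      }
    }
  }
  if (any(!genes$chrom %in% names(chrom_lengths))) {
    stop("gene on chromosome absent from genome")
  }
  len <- unname(chrom_lengths[genes$chrom])
  genes |>
    mutate(
      tu_start = ifelse(.data$strand == "+", .data$start,
                        pmax(0L, .data$start - as.integer(downstream))),
      tu_end = ifelse(.data$strand == "+",
                      pmin(len, .data$end + as.integer(downstream)),
                      .data$end)
    ) |>
    mutate(tu_start = as.integer(.data$tu_start),
           tu_end = as.integer(.data$tu_end)) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
}

# Union of 0-based half-open intervals, sorted.
merge_intervals <- function(x) {
  if (nrow(x) <= 1) return(arrange(x, .data$start))
  x <- arrange(x, .data$start, .data$end)
  out_s <- x$start[1]; out_e <- x$end[1]
  res_s <- integer(0); res_e <- integer(0)
  for (i in 2:nrow(x)) {
    if (x$start[i] <= out_e) {
      out_e <- max(out_e, x$end[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- x$start[i]; out_e <- x$end[i]
    }
  }
  tibble(start = c(res_s, out_s), end = c(res_e, out_e))
}

#' @rdname read_gene_models
#' @param genes Gene-model tibble as returned by `read_gene_models()`.
#' @export
write_gene_models_gtf <- function(genes, path) {
  lines <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                      g$gene_id, g$gene_id)
    ex <- g$exons[[1]]
    c(
      sprintf("%s\tclipmap\tgene\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, g$start + 1L, g$end, g$strand, attr_g),
      sprintf("%s\tclipmap\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, g$start + 1L, g$end, g$strand, attr_t),
      if (nrow(ex)) sprintf("%s\tclipmap\texon\t%d\t%d\t.\t%s\t.\t%s",
                            g$chrom, ex$start + 1L, ex$end, g$strand, attr_t)
    )
  }))
  readr::write_lines(lines, path)
  invisible(path)
}
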