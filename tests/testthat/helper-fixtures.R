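# Small hand-built fixtures and a per-session cache for the heavier
# synthetic runs shared between test files.

# one + strand and one - strand gene on separate small chromosomes
tiny_genes <- function(chrom_len = 13000L) {
  tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = c("c1", "c2"),
    strand = c("+", "-"),
    start = c(50L, chrom_len - 50L - 2000L),
    end = c(2050L, chrom_len - 50L),
    tu_start = c(50L, max(0L, chrom_len - 50L - 2000L - 10000L)),
    tu_end = c(pmin(chrom_len, 2050L + 10000L), chrom_len - 50L),
    exons = list(tibble::tibble(start = c(150L, 1050L), end = c(350L, 1250L)),
                 tibble::tibble(start = chrom_len - 50L - c(1250L, 350L),
                                end = chrom_len - 50L - c(1050L, 150L)))
  )
}

tiny_genome <- function(chrom_len = 13000L, seed = 42L) {
  withr::with_seed(seed, {
    g <- c(
      c1 = paste(sample(c("A", "C", "G", "T"), chrom_len, TRUE), collapse = ""),
      c2 = paste(sample(c("A", "C", "G", "T"), chrom_len, TRUE), collapse = "")
    )
    g
  })
}

make_reads <- function(chrom, start, end, strand = "+", condition = "MN",
                       replicate = 1L, id_prefix = "r") {
  n <- max(length(start), length(chrom))
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)), strand = rep_len(strand, n),
    condition = rep_len(condition, n),
    replicate = as.integer(rep_len(replicate, n)),
    read_id = paste0(id_prefix, seq_len(n))
  )
}

# cache of full synthetic pipeline runs keyed by seed; shared by the
# parameter-recovery and RNA-map suites
.clipmap_test_cache <- new.env(parent = emptyenv())

cached_pipeline_run <- function(seed, n_genes = 100L) {
  key <- sprintf("run_%d_%d", seed, n_genes)
  if (!is.null(.clipmap_test_cache[[key]])) {
    return(.clipmap_test_cache[[key]])
  }
  params <- simulation_params(n_genes = n_genes, seed = seed)
  sim <- simulate_clip_experiment(params)
  bind <- run_differential_binding(sim$reads, sim$genes, sim$genome)
  events <- run_splicing_analysis(sim$junctions)
  preds <- predict_splicing_direction(bind$sites, sim$truth$splicing)
  run <- list(sim = sim, sites = bind$sites,
              jps = bind$jps, events = events, predictions = preds)
  .clipmap_test_cache[[key]] <- run
  run
}

# overlap of an interval set with truth site rows
overlaps_site <- function(chrom, start, end, sites) {
  vapply(seq_along(chrom), function(i) {
    any(sites$chrom == chrom[i] & sites$start < end[i] & sites$end > start[i])
  }, logical(1))
}

# a genome whose positions 200.. carry chosen pentamers lets us control the
# downstream 5-mer of reads ending at 200
pentamer_fixture <- function(pentamers, n_each, filler = "A") {
  chrom_len <- 400L
  reads <- list()
  genome <- character(0)
  for (i in seq_along(pentamers)) {
    base <- paste(rep(filler, chrom_len), collapse = "")
    substr(base, 201, 205) <- pentamers[i]
    genome[sprintf("p%d", i)] <- base
    reads[[i]] <- make_reads(sprintf("p%d", i), seq_len(n_each[i]) + 99L,
                             200L, "+", "MN", 1L,
                             id_prefix = sprintf("p%d_", i))
  }
  list(genome = genome, reads = dplyr::bind_rows(reads))
}

# i.i.d. uniform genome with randomly placed odd-width null peaks
null_peakset <- function(n, chrom_len = 4000L, n_chroms = 40L, seed = 5L) {
  withr::with_seed(seed, {
    genome <- setNames(vapply(seq_len(n_chroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), chrom_len, TRUE), collapse = "")
    }, character(1)), sprintf("n%d", seq_len(n_chroms)))
    centre <- sample(500:(chrom_len - 500), n, TRUE)
    # odd widths keep the floor midpoint exact under coordinate mirroring
    peaks <- tibble::tibble(
      chrom = sample(names(genome), n, TRUE),
      start = centre - 25L, end = centre + 26L,
      strand = sample(c("+", "-"), n, TRUE)
    )
    list(genome = genome, peaks = peaks)
  })
}
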