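one_gene <- function(tu_len = 1000L, strand = "+") {
  tibble::tibble(
    gene_id = "g1", chrom = "c1", strand = strand,
    start = 0L, end = tu_len, tu_start = 0L, tu_end = tu_len,
    exons = list(tibble::tibble(start = integer(0), end = integer(0)))
  )
}

test_that("a stack of reads forms one significant peak; tiled reads none", {
  gene <- one_gene(1000L)
  stacked <- make_reads("c1", rep(400L, 20), rep(450L, 20))
  pk <- call_peaks(stacked, gene, alpha = 0.01)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$read_count, 20L)
  expect_equal(pk$summit_height, 20L)
  expect_lte(pk$p_value, 0.01)
  expect_equal(pk$start, 400L)
  expect_equal(pk$end, 450L)
  # 20 non-overlapping tiled reads: coverage never exceeds 1, no peak
  tiled <- make_reads("c1", seq(0, 950, by = 50), seq(50, 1000, by = 50))
  expect_equal(nrow(call_peaks(tiled, gene, alpha = 0.01)), 0L)
  # no reads, no peaks; empty unit errors
  expect_equal(nrow(call_peaks(stacked[0, ], gene)), 0L)
  bad <- gene
  bad$tu_end <- bad$tu_start
  expect_error(call_peaks(stacked, bad), "empty transcription unit")
})

test_that("biological complexity counts distinct contributing replicates", {
  gene <- one_gene()
  pk <- tibble::tibble(chrom = "c1", start = 100L, end = 200L, strand = "+")
  r <- dplyr::bind_rows(
    make_reads("c1", 120L, 170L, replicate = 1L, id_prefix = "a"),
    make_reads("c1", 130L, 180L, replicate = 1L, id_prefix = "b"),
    make_reads("c1", 140L, 190L, replicate = 3L, id_prefix = "c"),
    make_reads("c1", 700L, 760L, replicate = 5L, id_prefix = "d")
  )
  expect_equal(biological_complexity(pk, r), 2L)
  expect_equal(biological_complexity(pk, r[4, ]), 0L)
  r8 <- dplyr::bind_rows(lapply(1:8, function(i) {
    make_reads("c1", 120L, 170L, replicate = i, id_prefix = paste0("x", i))
  }))
  expect_equal(biological_complexity(pk, r8), 8L)
})

test_that("joint peaks obey the either-group complexity rule", {
  gene <- one_gene(2000L)
  gene$end <- 2000L
  # 4 MN replicates stacked at one locus, zero WSC reads: retained
  mn4 <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_reads("c1", rep(500L, 8), rep(560L, 8), condition = "MN",
               replicate = i, id_prefix = paste0("m", i))
  }))
  jp <- define_joint_peaks(mn4, gene)
  expect_equal(nrow(jp), 1L)
  expect_gt(jp$m, 0)
  expect_equal(jp$n, 0L)
  expect_true(all(jp$bc_mn >= 4 | jp$bc_wsc >= 2))
  # 1 MN and 1 WSC replicate only: dropped
  thin <- dplyr::bind_rows(
    make_reads("c1", rep(500L, 12), rep(560L, 12), condition = "MN",
               replicate = 1L, id_prefix = "m"),
    make_reads("c1", rep(500L, 12), rep(560L, 12), condition = "WSC",
               replicate = 1L, id_prefix = "w")
  )
  expect_equal(nrow(define_joint_peaks(thin, gene)), 0L)
  # replicate labels beyond the configured design are rejected
  bad <- make_reads("c1", 500L, 560L, condition = "MN", replicate = 9L)
  expect_error(define_joint_peaks(bad, gene), "replicate labels")
})

test_that("M and N sum the gene's same-class joint-peak counts", {
  gene <- one_gene(3000L)
  gene$end <- 3000L
  mk <- function(pos, n_mn, n_wsc) {
    dplyr::bind_rows(
      lapply(1:4, function(i) {
        make_reads("c1", rep(pos, n_mn), rep(pos + 60L, n_mn),
                   condition = "MN", replicate = i,
                   id_prefix = sprintf("m%d_%d", pos, i))
      }),
      lapply(1:2, function(i) {
        make_reads("c1", rep(pos, n_wsc), rep(pos + 60L, n_wsc),
                   condition = "WSC", replicate = i,
                   id_prefix = sprintf("w%d_%d", pos, i))
      })
    )
  }
  reads <- dplyr::bind_rows(mk(500L, 30L, 10L), mk(1500L, 10L, 10L))
  jp <- define_joint_peaks(reads, gene)
  expect_equal(nrow(jp), 2L)
  expect_equal(sort(jp$m), c(40L, 120L))
  expect_equal(unique(jp$M), 160L)
  expect_equal(unique(jp$N), 40L)
  expect_true(all(jp$region_class == "intron"))
})

test_that("downsampling is seeded, bounded and order-stable", {
  r <- make_reads("c1", 1:50 * 10L, 1:50 * 10L + 40L)
  expect_identical(downsample_reads(r, 50L), r)
  expect_equal(nrow(downsample_reads(r, 0L)), 0L)
  a <- downsample_reads(r, 20L, seed = 4L)
  b <- downsample_reads(r, 20L, seed = 4L)
  expect_identical(a, b)
  expect_false(is.unsorted(match(a$read_id, r$read_id)))
  expect_error(downsample_reads(r, 51L), "exceeds")
})

test_that("replicate-group correlation is scale-free and near zero on noise", {
  pk <- tibble::tibble(chrom = "c1", start = 1:1000 * 100L,
                       end = 1:1000 * 100L + 50L, strand = "+",
                       normalized_height = rexp(1000) + 1)
  expect_equal(replicate_group_correlation(pk, pk), 1.0)
  scaled <- pk
  scaled$normalized_height <- pk$normalized_height * 3
  # log-scale correlation ignores multiplicative depth differences, minus
  # the small distortion of the +0.5 offset
  expect_gt(replicate_group_correlation(pk, scaled), 0.99)
  withr::with_seed(8, {
    a <- pk; b <- pk
    a$normalized_height <- rpois(1000, 20)
    b$normalized_height <- rpois(1000, 20)
    expect_lt(replicate_group_correlation(a, b), 0.05)
  })
  expect_error(replicate_group_correlation(pk[1:2, ], pk[1:2, ]), "matched")
})

test_that("shifting the genome shifts every called coordinate equally", {
  k <- 137L
  p <- simulation_params(n_genes = 4L, seed = 17L)
  sim <- simulate_clip_experiment(p)
  pk1 <- call_peaks(sim$reads, sim$genes, alpha = 0.01)
  shifted_reads <- dplyr::mutate(sim$reads, start = start + k, end = end + k)
  shifted_genes <- dplyr::mutate(
    sim$genes, start = start + k, end = end + k,
    tu_start = tu_start + k, tu_end = tu_end + k,
    exons = lapply(exons, function(e) dplyr::mutate(e, start = start + k,
                                                    end = end + k))
  )
  pk2 <- call_peaks(shifted_reads, shifted_genes, alpha = 0.01)
  expect_equal(pk2$start, pk1$start + k)
  expect_equal(pk2$end, pk1$end + k)
  expect_equal(pk2$p_value, pk1$p_value)
  expect_equal(pk2$region_class, pk1$region_class)
})
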