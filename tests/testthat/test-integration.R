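site_row <- function(jp_id, start, end, call, fdr, gene_id = "g1",
                     chrom = "c1", strand = "+") {
  tibble::tibble(jp_id = jp_id, gene_id = gene_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, region_class = "intron",
                 call = call, fdr = fdr)
}

exon_event <- function(event_id = "ev1", exon_start = 5000L,
                       exon_end = 5100L, strand = "+", gene_id = "g1",
                       chrom = "c1") {
  tibble::tibble(event_id = event_id, gene_id = gene_id, chrom = chrom,
                 strand = strand, exon_start = as.integer(exon_start),
                 exon_end = as.integer(exon_end))
}

test_that("binding position and direction compose into the map prediction", {
  ev <- exon_event()
  # over-represented site 109 nt upstream of the exon: repression
  up <- site_row("s1", 4875, 4907, "over", 0.046)
  p1 <- predict_splicing_direction(up, ev)
  expect_equal(p1$offset, -109L)
  expect_equal(p1$predicted_direction, -1L)
  # over-represented site 121 nt downstream: activation
  down <- site_row("s2", 5204, 5236, "over", 1e-6)
  p2 <- predict_splicing_direction(down, ev)
  expect_equal(p2$offset, 121L)
  expect_equal(p2$predicted_direction, 1L)
  # under-represented binding flips the sign
  p3 <- predict_splicing_direction(
    site_row("s3", 4875, 4907, "under", 0.01), ev)
  expect_equal(p3$predicted_direction, 1L)
  # beyond the 400-nt hotspot: no prediction
  far <- site_row("s4", 4484, 4516, "over", 0.001)
  expect_equal(nrow(predict_splicing_direction(far, ev)), 0L)
  # untested/unchanged sites never predict
  expect_equal(nrow(predict_splicing_direction(
    site_row("s5", 4875, 4907, "unchanged", 0.5), ev)), 0L)
})

test_that("minus-strand offsets mirror the genomic layout", {
  ev <- exon_event(strand = "-")
  # genomically right of the exon = upstream on the minus strand
  up <- site_row("s1", 5204, 5236, "over", 0.01, strand = "-")
  p <- predict_splicing_direction(up, ev)
  expect_equal(p$offset, -121L)
  expect_equal(p$predicted_direction, -1L)
})

test_that("conflicting in-hotspot sites resolve by smallest FDR", {
  ev <- exon_event()
  sites <- dplyr::bind_rows(
    site_row("weak", 4875, 4907, "over", 0.08),
    site_row("strong", 5204, 5236, "over", 0.001)
  )
  p <- predict_splicing_direction(sites, ev)
  expect_equal(p$site_id, "strong")
  expect_equal(p$predicted_direction, 1L)
  tie <- dplyr::bind_rows(
    site_row("a", 4875, 4907, "over", 0.01),
    site_row("b", 5204, 5236, "over", 0.01)
  )
  expect_equal(nrow(predict_splicing_direction(tie, ev)), 0L)
})

test_that("concordance counts sign agreement among significant events", {
  preds <- tibble::tibble(
    event_id = sprintf("e%d", 1:9), site_id = "s", offset = -100L,
    predicted_direction = c(rep(-1L, 5), rep(1L, 4)), site_fdr = 0.01
  )
  events <- tibble::tibble(
    event_id = sprintf("e%d", 1:9),
    dI = c(-0.4, -0.3, -0.2, -0.5, 0.3, 0.2, 0.4, 0.1, 0.6),
    fdr = 0.001, kind = "cassette"
  )
  cc <- evaluate_concordance(preds, events)
  expect_equal(cc$n_predicted, 9L)
  expect_equal(cc$n_concordant, 8L)
  expect_equal(cc$fraction, 8 / 9, tolerance = 1e-12)
  # non-significant events drop out; none left gives NA
  events$fdr <- 1
  expect_true(is.na(evaluate_concordance(preds, events)$fraction))
})

test_that("set overlap reproduces the worked hypergeometric example", {
  ov <- overlap_enrichment(626, 1620, 5418, overlap = 281)
  expect_equal(ov$expected, 626 * 1620 / 5418, tolerance = 1e-12)
  expect_lt(ov$p_value, 2.2e-16)
  expect_equal(ov$p_value, oracle_hyper_tail(5418, 1620, 626, 281),
               tolerance = 1e-9)
  # character-set interface and subset validation
  u <- sprintf("g%d", 1:100)
  ov2 <- overlap_enrichment(u[1:30], u[21:50], u)
  expect_equal(ov2$overlap, 10L)
  expect_error(overlap_enrichment(c(u[1], "zzz"), u[1:5], u), "subsets")
  # disjoint sets: observed zero, p = 1
  expect_equal(overlap_enrichment(u[1:10], u[11:20], u)$p_value, 1)
  # overlap at expectation sits mid-distribution
  mid <- overlap_enrichment(100, 100, 1000, overlap = 10)
  expect_gt(mid$p_value, 0.3)
  expect_lt(mid$p_value, 0.8)
  # monotone: more overlap never raises the p-value
  ps <- vapply(10:30, function(k) {
    overlap_enrichment(100, 100, 1000, overlap = k)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("gene-set enrichment flags a planted set and skips empty ones", {
  withr::with_seed(31, {
    background <- sprintf("g%d", 1:400)
    planted <- sample(background, 60)
    targets <- unique(c(sample(planted, 35), sample(background, 25)))
    sets <- list(planted = planted,
                 random1 = sample(background, 60),
                 random2 = sample(background, 60),
                 outside = c("x1", "x2"))
    expect_warning(res <- gene_set_enrichment(targets, background, sets),
                   "no background member")
    expect_equal(res$set[1], "planted")
    expect_lt(res$fdr[1], 0.05)
    expect_false("outside" %in% res$set)
    # the target set itself is maximally enriched
    res2 <- gene_set_enrichment(targets, background,
                                list(self = targets, other = planted))
    expect_equal(res2$set[1], "self")
    expect_error(gene_set_enrichment(c("nope"), background, sets), "subset")
    expect_error(gene_set_enrichment(targets, character(0), sets), "empty")
  })
})

test_that("category concordance compares against the global direction mix", {
  enr <- tibble::tibble(
    gene_id = sprintf("g%d", 1:40),
    direction = c(rep("enriched", 20), rep("depleted", 20))
  )
  cats <- tibble::tibble(
    gene_id = sprintf("g%d", c(1:10, 21:30, 31:34)),
    category = c(rep("balanced", 10), rep("balanced", 10), rep("down", 4))
  )
  cc <- category_concordance(cats, enr)
  bal <- cc[cc$category == "balanced", ]
  expect_equal(bal$n_enriched, 10L)
  expect_equal(bal$n_depleted, 10L)
  expect_equal(bal$fraction_enriched, 0.5)
  expect_equal(bal$p_value, 1) # exactly the global proportion
  down <- cc[cc$category == "down", ]
  expect_equal(down$fraction_enriched, 0)
  expect_lt(down$p_value, 0.05)
  # the printed arithmetic: 42 of 55 is 76%
  expect_equal(round(100 * 42 / 55), 76)
  # category without directional genes gets an NA p-value
  cats2 <- tibble::tibble(gene_id = "g999", category = "empty")
  cc2 <- category_concordance(cats2, enr)
  expect_true(is.na(cc2$p_value))
})
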