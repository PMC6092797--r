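cassette_counts <- function(mn, wsc, reps = 1L) {
  # mn/wsc are c(i1, i2, e) per replicate
  dplyr::bind_rows(lapply(seq_len(reps), function(r) {
    tibble::tibble(event_id = "ev1", gene_id = "g1", kind = "cassette",
                   condition = c("MN", "WSC"), replicate = r,
                   i1 = c(mn[1], wsc[1]), i2 = c(mn[2], wsc[2]),
                   e = c(mn[3], wsc[3]),
                   ale1 = NA_integer_, ale2 = NA_integer_)
  }))
}

test_that("cassette quantification reproduces psi, dI and the Fisher p", {
  ev <- quantify_cassette(cassette_counts(c(30, 30, 10), c(10, 10, 30)))
  expect_equal(ev$psi_mn, 0.75)
  expect_equal(ev$psi_wsc, 0.25)
  expect_equal(ev$dI, 0.5)
  expect_equal(ev$p_value, oracle_fisher(30, 10, 10, 30))
  expect_true(ev$expressed)
  # identical counts: no change, p = 1
  same <- quantify_cassette(cassette_counts(c(20, 20, 20), c(20, 20, 20)))
  expect_equal(same$dI, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$bc_consistent)
})

test_that("the expressed rule is strictly over the junction minimum", {
  # pooled coverage exactly 10 in MN: not expressed, no test
  ev <- quantify_cassette(cassette_counts(c(6, 6, 4), c(30, 30, 30)))
  expect_equal(ev$I_MN + ev$E_MN, 10)
  expect_false(ev$expressed)
  expect_true(is.na(ev$p_value))
  # one junction read more crosses the threshold
  ev2 <- quantify_cassette(cassette_counts(c(6, 6, 5), c(30, 30, 30)))
  expect_true(ev2$expressed)
  # a condition with zero coverage is unexpressed, never an error
  ev3 <- quantify_cassette(cassette_counts(c(0, 0, 0), c(30, 30, 30)))
  expect_false(ev3$expressed)
})

test_that("ALE usage follows the pooled two-exon split", {
  counts <- tibble::tibble(
    event_id = "a1", gene_id = "g1", kind = "ale",
    condition = c("MN", "WSC"), replicate = 1L,
    i1 = NA_integer_, i2 = NA_integer_, e = NA_integer_,
    ale1 = c(130L, 44L), ale2 = c(70L, 156L)
  )
  ev <- quantify_ale(counts)
  expect_equal(ev$psi_mn, 0.65)
  expect_equal(ev$psi_wsc, 0.22)
  expect_equal(ev$dI, 0.43)
  expect_equal(ev$p_value, oracle_fisher(130, 70, 44, 156))
  expect_lt(ev$p_value, 1e-10)
  eq <- counts
  eq$ale1 <- c(50L, 50L); eq$ale2 <- c(50L, 50L)
  ev2 <- quantify_ale(eq)
  expect_equal(ev2$dI, 0)
  expect_equal(ev2$p_value, 1)
})

test_that("swapping condition labels negates dI and preserves the p-value", {
  counts <- cassette_counts(c(25, 31, 12), c(14, 12, 40), reps = 2L)
  fwd <- quantify_cassette(counts)
  swapped <- counts
  swapped$condition <- ifelse(counts$condition == "MN", "WSC", "MN")
  rev <- quantify_cassette(swapped)
  expect_equal(rev$dI, -fwd$dI)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("biological consistency requires every replicate pair to agree", {
  concordant <- dplyr::bind_rows(
    cassette_counts(c(30, 30, 10), c(10, 10, 30), reps = 1L),
    dplyr::mutate(cassette_counts(c(28, 30, 11), c(12, 10, 28)),
                  replicate = 2L)
  )
  expect_true(quantify_cassette(concordant)$bc_consistent)
  discordant <- concordant
  # second MN replicate flipped below every WSC replicate
  discordant[discordant$condition == "MN" & discordant$replicate == 2L,
             c("i1", "i2", "e")] <- list(2L, 2L, 40L)
  expect_false(quantify_cassette(discordant)$bc_consistent)
})

test_that("FDR families contain only expressed events of the same kind", {
  counts <- dplyr::bind_rows(
    cassette_counts(c(30, 30, 10), c(10, 10, 30)),
    dplyr::mutate(cassette_counts(c(2, 2, 3), c(1, 2, 2)),
                  event_id = "thin"),
    tibble::tibble(event_id = "a1", gene_id = "g2", kind = "ale",
                   condition = c("MN", "WSC"), replicate = 1L,
                   i1 = NA_integer_, i2 = NA_integer_, e = NA_integer_,
                   ale1 = c(120L, 40L), ale2 = c(80L, 160L))
  )
  ev <- run_splicing_analysis(counts)
  expect_true(is.na(ev$fdr[ev$event_id == "thin"]))
  expect_false(ev$significant[ev$event_id == "thin"])
  # a single expressed event per kind keeps fdr = p
  expect_equal(ev$fdr[ev$event_id == "ev1"], ev$p_value[ev$event_id == "ev1"])
  expect_equal(ev$fdr[ev$event_id == "a1"], ev$p_value[ev$event_id == "a1"])
  # ALE significance needs the effect-size rule too
  expect_true(abs(ev$dI[ev$event_id == "a1"]) >= 0.2)
})

test_that("ALE calls respect the |dI| threshold", {
  # strong p but small usage shift: significant for cassette rules, not ALE
  counts <- tibble::tibble(
    event_id = "a1", gene_id = "g1", kind = "ale",
    condition = c("MN", "WSC"), replicate = 1L,
    i1 = NA_integer_, i2 = NA_integer_, e = NA_integer_,
    ale1 = c(5500L, 5000L), ale2 = c(4500L, 5000L)
  )
  ev <- run_splicing_analysis(counts)
  expect_lt(ev$fdr, 0.1)
  expect_lt(abs(ev$dI), 0.2)
  expect_false(ev$significant)
})

test_that("the dI estimator is unbiased and gains from coverage", {
  withr::with_seed(71, {
    # bias at per-replicate coverage 100, true dI = 0.3
    n <- 500
    sim_ev <- function(cov, psi_mn, psi_wsc, id) {
      tibble::tibble(
        event_id = id, gene_id = id, kind = "cassette",
        condition = rep(c("MN", "WSC"), each = 2),
        replicate = rep(1:2, 2),
        i1 = rbinom(4, cov, rep(c(psi_mn, psi_wsc), each = 2)),
        i2 = rbinom(4, cov, rep(c(psi_mn, psi_wsc), each = 2)),
        e = rbinom(4, cov, 1 - rep(c(psi_mn, psi_wsc), each = 2)),
        ale1 = NA_integer_, ale2 = NA_integer_
      )
    }
    counts <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      sim_ev(100L, 0.6, 0.3, sprintf("e%d", i))
    }))
    ev <- quantify_cassette(counts)
    expect_lt(abs(mean(ev$dI) - 0.3), 0.02)
    # median p never increases with coverage at fixed true dI
    med_p <- vapply(c(25L, 50L, 100L, 200L), function(cov) {
      counts <- dplyr::bind_rows(lapply(seq_len(150), function(i) {
        sim_ev(cov, 0.55, 0.4, sprintf("c%d_%d", cov, i))
      }))
      stats::median(quantify_cassette(counts)$p_value, na.rm = TRUE)
    }, numeric(1))
    expect_true(all(diff(med_p) <= 1e-12))
  })
})
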