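#' Parameters for the synthetic CLIP experiment
#'
#' Defaults emulate the study design the pipeline was built for: two CLIP
#' conditions with unequal replicate counts (8 MN vs 4 WSC biological
#' replicates), an MN library roughly one eighth the depth of WSC, cDNA insert
#' lengths of 30-80 nt, YCAY-dense planted binding sites with
#' condition-specific intensity multipliers, reverse-transcription artifact
#' reads whose 3' ends abut genomic GTGTC pentamers, and junction-count tables
#' whose inclusion shifts are coupled to the planted binding changes through
#' the position-dependent RNA map (upstream binding gain represses inclusion,
#' downstream binding gain activates it).
#'
#' @param n_genes Number of genes (each on its own chromosome).
#' @param gene_length Range (min, max) of gene span in nt.
#' @param n_replicates Named (MN, WSC) CLIP replicate counts.
#' @param depth Named (MN, WSC) mean CLIP reads per gene per condition.
#' @param read_length Range of read lengths in nt.
#' @param background_fraction Probability a non-artifact read is uniform
#'   background within the transcription unit.
#' @param artifact_fraction Probability a read is an RT artifact.
#' @param sites_per_gene Planted YCAY cluster sites per gene.
#' @param differential_fraction Probability a gene carries one site with a
#'   condition-specific intensity multiplier.
#' @param fold_levels MN intensity multipliers for differential sites
#'   (values > 1 are over-represented in MN, < 1 under-represented).
#' @param cassette_fraction Probability a gene carries a cassette-exon event.
#' @param ale_fraction Probability a gene carries an alternative last exon
#'   pair.
#' @param ale_differential_fraction Fraction of ALE genes with differential
#'   usage between conditions.
#' @param coupled_ddI Range of the absolute inclusion shift |dI| for events
#'   coupled to a differential site.
#' @param splicing_replicates RNA-seq replicates per condition.
#' @param splicing_depth Mean junction coverage per event per replicate.
#' @param base_probs Background base composition (A, C, G, T).
#' @param seed Integer seed; all generator stages are deterministic given it.
#' @return A list of class `clip_sim_params`.
#' @export
simulation_params <- function(n_genes = 200L,
                              gene_length = c(4000L, 6000L),
                              n_replicates = c(MN = 8L, WSC = 4L),
                              depth = c(MN = 200, WSC = 1600),
                              read_length = c(30L, 80L),
                              background_fraction = 0.3,
                              artifact_fraction = 0.05,
                              sites_per_gene = 6L,
                              differential_fraction = 0.3,
                              fold_levels = c(4, 0.25),
                              cassette_fraction = 0.6,
                              ale_fraction = 0.3,
                              ale_differential_fraction = 0.3,
                              coupled_ddI = c(0.2, 0.5),
                              splicing_replicates = 2L,
                              splicing_depth = 100,
                              base_probs = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                              seed = 1L) {
  p <- as.list(environment())
  fr <- c(p$background_fraction, p$artifact_fraction, p$differential_fraction,
          p$cassette_fraction, p$ale_fraction, p$ale_differential_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (any(p$fold_levels <= 0)) stop("fold_levels must be positive")
  if (abs(sum(p$base_probs) - 1) > 1e-8) stop("base_probs must sum to 1")
  structure(p, class = "clip_sim_params")
}

# fixed transcript-local exon layout (0 = 5' end of the gene span):
# e1 [100,300) constitutive; e2 [1200,1300) cassette; e3 [2200,2400)
# constitutive; last exons ALE1 [L-1200,L-900) and (if present) ALE2
# [L-400,L-100).
gene_layout <- function(L) {
  if (L < 3600) stop("gene length too small to host requested exons")
  list(
    e1 = c(100L, 300L), e2 = c(1200L, 1300L), e3 = c(2200L, 2400L),
    ale1 = c(L - 1200L, L - 900L), ale2 = c(L - 400L, L - 100L),
    introns = rbind(c(300L, 1200L), c(1300L, 2200L), c(2400L, L - 1200L))
  )
}

# transcript-local [tstart, tend) -> genomic (0-based half-open), relative to
# the transcription-unit 5' end
local_to_genomic <- function(tstart, tend, strand, tu_start, tu_end) {
  if (strand == "+") cbind(tu_start + tstart, tu_start + tend)
  else cbind(tu_end - tend, tu_end - tstart)
}

#' Generate a synthetic genome, gene models and planted truth
#'
#' Each gene sits on its own chromosome with an i.i.d. background sequence;
#' planted sites are 32-nt YCAY-dense clusters (eight overlapping-free YCAY
#' occurrences) written into intronic sequence. For genes carrying both a
#' differential site and a cassette event the site is placed inside the 400-nt
#' hotspot flanking the cassette exon and the event's inclusion shift follows
#' the RNA-map direction rule; the rule is asserted on the emitted truth.
#'
#' @param params A [simulation_params()] object.
#' @return A list with `genome` (named character vector), `genes` (gene-model
#'   tibble as from [read_gene_models()]) and `truth`, a list of tibbles:
#'   `sites`, `splicing`, `ale`, plus `gene_weights`.
#' @export
generate_genome_and_genes <- function(params) {
  withr::with_seed(params$seed, generate_genome_impl(params))
}

generate_genome_impl <- function(params) {
  n <- params$n_genes
  site_len <- 32L
  cluster <- strrep("TCAT", site_len / 4L)
  bases <- names(params$base_probs)

  genome <- character(n)
  chroms <- sprintf("chr%d", seq_len(n))
  gene_rows <- vector("list", n)
  site_rows <- vector("list", n)
  cass_rows <- vector("list", n)
  ale_rows <- vector("list", n)
  weights <- rlnorm(n, 0, 0.4)

  for (g in seq_len(n)) {
    L <- sample(params$gene_length[1]:params$gene_length[2], 1L)
    lay <- gene_layout(L)
    strand <- if (g %% 2L == 1L) "+" else "-"
    chrom_len <- L + 10000L + 100L
    if (strand == "+") {
      gstart <- 50L; gend <- gstart + L
      tu_start <- gstart; tu_end <- min(chrom_len, gend + 10000L)
    } else {
      gend <- chrom_len - 50L; gstart <- gend - L
      tu_start <- max(0L, gstart - 10000L); tu_end <- gend
    }
    seq_g <- paste(sample(bases, chrom_len, TRUE, prob = params$base_probs),
                   collapse = "")

    has_cass <- runif(1) < params$cassette_fraction
    has_ale <- runif(1) < params$ale_fraction
    is_diff <- params$sites_per_gene > 0 &&
      runif(1) < params$differential_fraction

    # choose site centres in introns, min separation 300 nt
    coupled <- is_diff && has_cass
    centres <- integer(0)
    if (coupled) {
      side <- sample(c("up", "down"), 1L)
      centres <- if (side == "up") {
        sample(seq(lay$e2[1] - 370L, lay$e2[1] - 30L), 1L)
      } else {
        sample(seq(lay$e2[2] + 30L, lay$e2[2] + 370L), 1L)
      }
    }
    cand <- unlist(apply(lay$introns, 1, function(iv) {
      if (iv[2] - iv[1] > 2L * site_len) {
        seq(iv[1] + site_len, iv[2] - site_len)
      }
    }))
    tries <- 0L
    while (length(centres) < params$sites_per_gene && tries < 500L) {
      tries <- tries + 1L
      x <- sample(cand, 1L)
      if (all(abs(x - centres) >= 250L)) centres <- c(centres, x)
    }
    n_sites <- length(centres)
    mult <- rep(1, n_sites)
    if (is_diff && n_sites > 0) {
      mult[1] <- sample(rep(params$fold_levels, 2L), 1L)
    }

    # write YCAY clusters into the sequence (transcript-strand oriented)
    if (n_sites > 0) {
      tstarts <- centres - site_len %/% 2L
      giv <- local_to_genomic(tstarts, tstarts + site_len, strand,
                              tu_start, tu_end)
      ins <- if (strand == "+") cluster else reverse_complement(cluster)
      for (k in seq_len(n_sites)) {
        substr(seq_g, giv[k, 1] + 1L, giv[k, 2]) <- ins
      }
      intens <- runif(n_sites, 0.8, 1.2)
      site_rows[[g]] <- tibble(
        site_id = sprintf("%s_s%d", chroms[g], seq_len(n_sites)),
        gene_id = sprintf("g%03d", g), chrom = chroms[g], strand = strand,
        start = as.integer(giv[, 1]), end = as.integer(giv[, 2]),
        tcenter = as.integer(centres),
        base_intensity = intens,
        mn_multiplier = mult,
        # true relative shares of the gene's site-anchored reads: the site
        # test is compositional, so a gain at one site depresses the true
        # relative share of the gene's other sites
        true_share_mn = intens * mult / sum(intens * mult),
        true_share_wsc = intens / sum(intens)
      )
    }

    # splicing truth
    if (has_cass) {
      e2g <- local_to_genomic(lay$e2[1], lay$e2[2], strand, tu_start, tu_end)
      psi_mn <- psi_wsc <- runif(1, 0.3, 0.7)
      coupled_site <- NA_character_
      if (coupled) {
        ddI <- runif(1, params$coupled_ddI[1], params$coupled_ddI[2])
        upstream <- centres[1] < lay$e2[1]
        over <- mult[1] > 1
        dir_neg <- (upstream && over) || (!upstream && !over)
        if (dir_neg) {
          psi_wsc <- runif(1, ddI + 0.05, 0.95)
          psi_mn <- psi_wsc - ddI
        } else {
          psi_wsc <- runif(1, 0.05, 0.95 - ddI)
          psi_mn <- psi_wsc + ddI
        }
        coupled_site <- sprintf("%s_s1", chroms[g])
      }
      cass_rows[[g]] <- tibble(
        event_id = sprintf("g%03d_cass", g), gene_id = sprintf("g%03d", g),
        chrom = chroms[g], strand = strand,
        exon_start = as.integer(e2g[1]), exon_end = as.integer(e2g[2]),
        psi_wsc = psi_wsc, psi_mn = psi_mn,
        coupled_site_id = coupled_site
      )
    }
    if (has_ale) {
      u_wsc <- u_mn <- runif(1, 0.2, 0.8)
      if (runif(1) < params$ale_differential_fraction) {
        d <- runif(1, 0.25, 0.5) * sample(c(-1, 1), 1L)
        u_wsc <- runif(1, max(0.05, 0.05 - d), min(0.95, 0.95 - d))
        u_mn <- u_wsc + d
      }
      ale_rows[[g]] <- tibble(
        event_id = sprintf("g%03d_ale", g), gene_id = sprintf("g%03d", g),
        usage_wsc = u_wsc, usage_mn = u_mn
      )
    }

    exons <- tibble(
      start = c(lay$e1[1], lay$e2[1], lay$e3[1], lay$ale1[1],
                if (has_ale) lay$ale2[1]),
      end = c(lay$e1[2], lay$e2[2], lay$e3[2], lay$ale1[2],
              if (has_ale) lay$ale2[2])
    )
    ex_g <- local_to_genomic(exons$start, exons$end, strand, tu_start, tu_end)
    gene_rows[[g]] <- tibble(
      gene_id = sprintf("g%03d", g), chrom = chroms[g], strand = strand,
      start = gstart, end = gend, tu_start = tu_start, tu_end = tu_end,
      exons = list(arrange(tibble(start = as.integer(ex_g[, 1]),
                                  end = as.integer(ex_g[, 2])), start))
    )
    genome[g] <- seq_g
  }
  names(genome) <- chroms

  truth <- list(
    sites = bind_rows(site_rows),
    splicing = bind_rows(cass_rows),
    ale = bind_rows(ale_rows),
    gene_weights = tibble(gene_id = sprintf("g%03d", seq_len(n)),
                          weight = weights)
  )
  assert_map_coupling(truth)
  list(genome = genome, genes = bind_rows(gene_rows), truth = truth)
}

# the coupling invariant: upstream gain => inclusion loss, downstream gain =>
# inclusion gain (and the reverse for binding loss)
assert_map_coupling <- function(truth) {
  sp <- truth$splicing
  if (is.null(sp) || !nrow(sp)) return(invisible(TRUE))
  cp <- sp[!is.na(sp$coupled_site_id), , drop = FALSE]
  if (!nrow(cp)) return(invisible(TRUE))
  st <- truth$sites[match(cp$coupled_site_id, truth$sites$site_id), ]
  centre <- (st$start + st$end) %/% 2L
  upstream <- ifelse(cp$strand == "+", centre < cp$exon_start,
                     centre >= cp$exon_end)
  over <- st$mn_multiplier > 1
  expect_neg <- (upstream & over) | (!upstream & !over)
  ok <- ifelse(expect_neg, cp$psi_mn < cp$psi_wsc, cp$psi_mn > cp$psi_wsc)
  if (!all(ok)) stop("planted splicing truth violates the RNA-map rule")
  invisible(TRUE)
}

#' Simulate CLIP reads for both conditions
#'
#' Per replicate and gene, the read count is Poisson with mean
#' `depth[condition] * gene_weight / n_replicates[condition]`. Each read is an
#' RT artifact (3' end abutting a transcript-strand GTGTC occurrence) with
#' probability `artifact_fraction`, otherwise uniform background within the
#' transcription unit with probability `background_fraction`, otherwise
#' anchored at a planted site chosen proportionally to
#' `base_intensity * mn_multiplier^(condition == "MN")`, with +/-10 nt jitter
#' around the site centre.
#'
#' @param genome,genes,truth Output of [generate_genome_and_genes()].
#' @param params The [simulation_params()] used.
#' @param seed Seed (defaults to `params$seed + 1`).
#' @return A list with `reads` (a read tibble as from [read_bed6()]) and
#'   `artifact_read_ids` (character vector of planted artifact reads).
#' @export
simulate_clip_reads <- function(genome, genes, truth, params,
                                seed = params$seed + 1L) {
  withr::with_seed(seed, simulate_reads_impl(genome, genes, truth, params))
}

simulate_reads_impl <- function(genome, genes, truth, params) {
  rl <- params$read_length
  # transcript-oriented TU sequences and their GTGTC occurrence lists
  tu_seq <- oriented_subseq(genome, genes$chrom, genes$tu_start, genes$tu_end,
                            genes$strand)
  occ <- gregexpr("GTGTC", tu_seq, fixed = TRUE)
  occ <- lapply(occ, function(x) if (x[1] == -1L) integer(0) else as.integer(x) - 1L)
  weights <- truth$gene_weights$weight[match(genes$gene_id,
                                             truth$gene_weights$gene_id)]
  sites_by_gene <- split(truth$sites, truth$sites$gene_id)

  out <- vector("list", 0)
  art_ids <- character(0)
  serial <- 0L
  for (cond in c("MN", "WSC")) {
    nrep <- params$n_replicates[[cond]]
    for (r in seq_len(nrep)) {
      for (g in seq_len(nrow(genes))) {
        lam <- params$depth[[cond]] * weights[g] / nrep
        nread <- rpois(1L, lam)
        if (nread == 0L) next
        tu_len <- genes$tu_end[g] - genes$tu_start[g]
        len <- sample(rl[1]:rl[2], nread, TRUE)
        u <- runif(nread)
        st <- truth$sites[0, ]
        gs <- sites_by_gene[[genes$gene_id[g]]]
        has_sites <- !is.null(gs) && nrow(gs) > 0
        is_art <- u < params$artifact_fraction & lengths(occ[g]) > 0
        is_bg <- !is_art & (u < params$artifact_fraction +
                              (1 - params$artifact_fraction) *
                              params$background_fraction | !has_sites)
        is_site <- !is_art & !is_bg
        tstart <- integer(nread)
        # background: uniform over the transcription unit
        nb <- sum(is_bg)
        if (nb) tstart[is_bg] <- floor(runif(nb, 0, pmax(1, tu_len - len[is_bg])))
        # site-anchored
        ns <- sum(is_site)
        if (ns) {
          w <- gs$base_intensity *
            ifelse(rep(cond == "MN", nrow(gs)), gs$mn_multiplier, 1)
          pick <- sample.int(nrow(gs), ns, TRUE, prob = w)
          centre <- gs$tcenter[pick] + sample(-10:10, ns, TRUE)
          tstart[is_site] <- centre - len[is_site] %/% 2L
        }
        # artifacts: 3' end abuts a GTGTC start
        na_ <- sum(is_art)
        if (na_) {
          o <- occ[[g]]
          o <- o[o >= rl[2] & o + 5L <= tu_len]
          if (length(o)) {
            e3 <- o[sample.int(length(o), na_, TRUE)]
            tstart[is_art] <- e3 - len[is_art]
          } else {
            is_bg[is_art] <- TRUE
            tstart[is_art] <- floor(runif(na_, 0, pmax(1, tu_len - len[is_art])))
            is_art[is_art] <- FALSE
          }
        }
        tstart <- pmin(pmax(tstart, 0L), tu_len - len)
        giv <- if (genes$strand[g] == "+") {
          cbind(genes$tu_start[g] + tstart, genes$tu_start[g] + tstart + len)
        } else {
          cbind(genes$tu_end[g] - tstart - len, genes$tu_end[g] - tstart)
        }
        ids <- sprintf("r%08d", serial + seq_len(nread))
        serial <- serial + nread
        art_ids <- c(art_ids, ids[is_art])
        out[[length(out) + 1L]] <- tibble(
          chrom = genes$chrom[g], start = as.integer(giv[, 1]),
          end = as.integer(giv[, 2]), strand = genes$strand[g],
          condition = cond, replicate = r, read_id = ids
        )
      }
    }
  }
  list(reads = bind_rows(out), artifact_read_ids = art_ids)
}

#' Simulate splice-junction count tables
#'
#' Per event, condition and replicate the junction coverage is Poisson with
#' mean `splicing_depth`; for cassette events the two inclusion-junction
#' counts and the skip-junction count are independent binomial draws at the
#' condition's true inclusion fraction, and for ALE events the reads split
#' binomially between the two last exons at the true usage.
#'
#' @param truth Truth list from [generate_genome_and_genes()].
#' @param params The [simulation_params()] used.
#' @param seed Seed (defaults to `params$seed + 2`).
#' @return A long tibble with `event_id`, `gene_id`, `kind`, `condition`,
#'   `replicate`, and counts `i1`, `i2`, `e` (cassette) or `ale1`, `ale2`.
#' @export
simulate_junction_counts <- function(truth, params, seed = params$seed + 2L) {
  withr::with_seed(seed, simulate_junctions_impl(truth, params))
}

simulate_junctions_impl <- function(truth, params) {
  grid <- tidyr::expand_grid(condition = c("MN", "WSC"),
                             replicate = seq_len(params$splicing_replicates))
  cass <- NULL
  if (!is.null(truth$splicing) && nrow(truth$splicing)) {
    cass <- tidyr::crossing(truth$splicing[, c("event_id", "gene_id",
                                               "psi_wsc", "psi_mn")], grid) |>
      mutate(
        psi = ifelse(.data$condition == "MN", .data$psi_mn, .data$psi_wsc),
        cov = rpois(n(), params$splicing_depth),
        i1 = rbinom(n(), .data$cov, .data$psi),
        i2 = rbinom(n(), .data$cov, .data$psi),
        e = rbinom(n(), .data$cov, 1 - .data$psi),
        kind = "cassette", ale1 = NA_integer_, ale2 = NA_integer_
      ) |>
      select("event_id", "gene_id", "kind", "condition", "replicate",
             "i1", "i2", "e", "ale1", "ale2")
  }
  ale <- NULL
  if (!is.null(truth$ale) && nrow(truth$ale)) {
    ale <- tidyr::crossing(truth$ale, grid) |>
      mutate(
        usage = ifelse(.data$condition == "MN", .data$usage_mn,
                       .data$usage_wsc),
        cov = rpois(n(), params$splicing_depth),
        ale1 = rbinom(n(), .data$cov, .data$usage),
        ale2 = .data$cov - .data$ale1,
        kind = "ale", i1 = NA_integer_, i2 = NA_integer_, e = NA_integer_
      ) |>
      select("event_id", "gene_id", "kind", "condition", "replicate",
             "i1", "i2", "e", "ale1", "ale2")
  }
  bind_rows(cass, ale)
}

#' Run the whole generator
#'
#' Convenience wrapper chaining [generate_genome_and_genes()],
#' [simulate_clip_reads()] and [simulate_junction_counts()]; fully
#' deterministic given `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @return A list with `genome`, `genes`, `reads`, `junctions`, `truth` and
#'   `params`; `truth$artifact_read_ids` holds the planted artifact reads and
#'   `truth$library_sizes` the realised per-condition/replicate read counts.
#' @export
simulate_clip_experiment <- function(params = simulation_params()) {
  gg <- generate_genome_and_genes(params)
  rr <- simulate_clip_reads(gg$genome, gg$genes, gg$truth, params)
  jx <- simulate_junction_counts(gg$truth, params)
  truth <- gg$truth
  truth$artifact_read_ids <- rr$artifact_read_ids
  truth$library_sizes <- rr$reads |>
    count(.data$condition, .data$replicate, name = "n_reads")
  list(genome = gg$genome, genes = gg$genes, reads = rr$reads,
       junctions = jx, truth = truth, params = params)
}
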