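# Permutation enrichment, mt-region enrichment, deletion-window correlation,
# nearest-feature distances and the chromosome-count regression.

enr_ref <- function()
  build_toy_references(c(chr1 = 100000, chr2 = 80000), mt_length = 16569,
                       seed = 21, mt_mode = "random")

ten_pct_track <- function(ref) {
  iv <- do.call(rbind, lapply(setdiff(names(ref$contigs), "MT"),
                              function(cc) {
    L <- nchar(ref_seq(ref, cc))
    s <- seq(0, L - 10000, by = 10000)
    data.frame(contig = cc, start = s, end = s + 1000)
  }))
  interval_track(iv, "ten_pct")
}

test_that("permutation p-values obey the add-one floor and reproducibility", {
  ref <- enr_ref()
  trk <- ten_pct_track(ref)
  # maximal-extremity construction: every flank inside the track
  pos <- data.frame(contig = "chr1", pos = rep(500L, 30))
  pe <- permutation_enrichment(pos, trk, ref, n_perm = 1000, seed = 3)
  expect_equal(pe$direction, "enriched")
  expect_equal(pe$empirical_p, 2 / 1001)       # floor: 2*(1+0)/(N+1)
  expect_gte(pe$empirical_p, 1 / 1001)

  pe2 <- permutation_enrichment(pos, trk, ref, n_perm = 1000, seed = 3)
  expect_identical(pe$null_counts, pe2$null_counts)

  # track covering the whole genome: observed = null always, p = 1
  all_iv <- do.call(rbind, lapply(setdiff(names(ref$contigs), "MT"),
                                  function(cc)
    data.frame(contig = cc, start = 0, end = nchar(ref_seq(ref, cc)))))
  full <- interval_track(all_iv, "full")
  pfull <- permutation_enrichment(pos, full, ref, n_perm = 200, seed = 1)
  expect_equal(pfull$empirical_p, 1)

  empty <- interval_track(data.frame(contig = character(0),
                                     start = integer(0), end = integer(0)),
                          "empty")
  pempty <- permutation_enrichment(pos, empty, ref, n_perm = 200, seed = 1)
  expect_true(is.na(pempty$empirical_p))
  expect_error(permutation_enrichment(pos, trk, ref, n_perm = 10), "n_perm")
})

test_that("mt region enrichment flags planted concentration and stays
           calibrated under the uniform null", {
  ref <- enr_ref()
  set.seed(5)
  # all breakpoints planted in the D-loop -> minimal p, enriched
  dl <- c(sample(16024:16569, 50, replace = TRUE),
          sample(1:576, 50, replace = TRUE))
  res <- mt_region_enrichment(dl, ref, n_perm = 500, seed = 2)
  drow <- res[res$region == "D-loop", ]
  expect_equal(drow$direction, "enriched")
  expect_equal(drow$empirical_p, 2 / 501)

  # a region table whose D-loop covers the whole genome: p = 1
  regions <- mt_region_table()
  full <- regions
  full[full$region == "D-loop", c("start", "end")] <-
    matrix(c(1, 16569, 1, 16569), nrow = 2)
  res_full <- mt_region_enrichment(sample(16569, 50, TRUE), ref,
                                   regions = full, n_perm = 200, seed = 2)
  expect_equal(res_full$empirical_p[res_full$region == "D-loop"], 1)

  # null calibration: uniform breakpoints rarely reach significance
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    r <- mt_region_enrichment(sample(16569, 80, TRUE), ref,
                              n_perm = 200, seed = s)
    mean(r$empirical_p > 0.05)
  }, 0)
  expect_gte(mean(hits >= 0.9), 0.9)

  bad <- mt_region_table()
  bad <- bad[bad$region != "OL", ]
  expect_error(mt_region_enrichment(1:10, ref, regions = bad),
               "configuration")
})

test_that("deletion-breakpoint window correlation behaves at the limits", {
  set.seed(8)
  pts <- sample(16569, 300, replace = TRUE)
  ident <- breakpoint_window_correlation(pts, pts, 16569)
  expect_equal(ident$r, 1)
  expect_equal(ident$n_windows, 166)

  # independent uniform sets: small |r| on average
  rs <- vapply(1:50, function(s) {
    set.seed(s)
    abs(breakpoint_window_correlation(sample(16569, 200, TRUE),
                                      sample(16569, 200, TRUE), 16569)$r)
  }, 0)
  expect_lt(mean(rs), 0.15)

  # half-genome shift of the same points: near-zero correlation
  shifted <- ((pts - 1 + 8284) %% 16569) + 1
  shift_r <- breakpoint_window_correlation(pts, shifted, 16569)$r
  expect_lt(abs(shift_r), 0.25)

  expect_true(is.na(breakpoint_window_correlation(integer(0), pts, 16569)$r))
})

test_that("nearest-feature distances and threshold enrichment", {
  ref <- enr_ref()
  trk <- interval_track(data.frame(contig = "chr1", start = 50000,
                                   end = 50100), "peak")
  pos <- data.frame(contig = c("chr1", "chr1", "chr2"),
                    pos = c(50050L, 47501L, 1000L))
  d <- distance_to_nearest_feature(pos, trk, ref, n_perm = 200, seed = 4)
  expect_equal(d$distances$distance[1], 0)         # inside the peak
  expect_equal(d$distances$distance[2], 2500)      # 2.5 kb upstream
  expect_equal(d$n_no_feature, 1L)                 # chr2 has no features
  within1k <- d$summary[d$summary$threshold == 1000, ]
  within3k <- d$summary[d$summary$threshold == 3000, ]
  expect_equal(within1k$within, 1L)
  expect_equal(within3k$within, 2L)

  # planted within-1kb placement is called enriched
  many <- data.frame(contig = "chr1", pos = seq(49500L, 50500L, by = 50L))
  e <- distance_to_nearest_feature(many, trk, ref, thresholds = 1000L,
                                   n_perm = 300, seed = 4)
  expect_equal(e$summary$direction, "enriched")
  expect_lt(e$summary$empirical_p, 0.05)
})

test_that("chromosome-count regression recovers parameters and flags
           collinearity", {
  set.seed(12)
  base <- data.frame(Lchr = runif(22, 50, 250))
  for (nm in c("Pcentro", "Pcpg", "Pline", "Pltr", "Pretroposon", "Psine",
               "Pmicrosat", "Prmsk", "Prepeats", "Pdups", "Preg"))
    base[[nm]] <- log2(runif(22, 0.01, 0.5))
  base$Nnumt <- 3 + 2 * base$Lchr          # noiseless linear truth
  fit <- suppressWarnings(chromosome_count_model(base))  # perfect-fit note
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "Lchr"],
               2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$length_p, 1e-10)

  dup <- base
  dup$Preg <- dup$Pline                    # duplicated covariate
  expect_error(chromosome_count_model(dup), "collinear")
  expect_error(chromosome_count_model(base[1:5, ]), "at least")
  expect_error(chromosome_count_model(base[, -1]), "missing columns")
})

test_that("enrichment test is calibrated under the uniform null", {
  # fraction of null tests with p < 0.05 should sit near 0.05
  ref <- enr_ref()
  trk <- ten_pct_track(ref)
  ps <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    pos <- data.frame(contig = sample(c("chr1", "chr2"), 40, TRUE),
                      pos = sample(70000L, 40))
    permutation_enrichment(pos, trk, ref, n_perm = 200,
                           seed = s)$empirical_p
  }, 0)
  frac <- mean(ps < 0.05)
  expect_lt(frac, 0.12)
})
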