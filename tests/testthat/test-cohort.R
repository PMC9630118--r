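# Cohort unification, frequency classes, known-NUMT matching and summaries.

fake_candidate <- function(sample, contig, start, mt_start, support = 5L,
                           width = 200L, mt_width = 400L) {
  data.frame(sample_id = sample, nuclear_contig = contig,
             nuclear_start = start, nuclear_end = start + width,
             mt_start = mt_start, mt_end = mt_start + mt_width,
             support = support, orientation = "+/-",
             candidate_id = sprintf("%s:%s:%d", sample, contig, start))
}

unification_ref <- function()
  build_toy_references(c(chr1 = 100000), mt_length = 16569, seed = 1,
                       mt_mode = "random")

test_that("cross-sample unification follows the 1 kb both-genome rule", {
  ref <- unification_ref()
  # same locus jittered across 10 samples -> one cohort NUMT, 10 carriers
  cands <- do.call(rbind, lapply(1:10, function(i)
    fake_candidate(sprintf("S%04d", i), "chr1", 5000 + i * 7, 2000 + i)))
  coh <- unify_cohort_numts(cands, ref)
  expect_equal(nrow(coh), 1)
  expect_equal(coh$n_carriers, 10L)

  # two loci 5 kb apart stay separate
  two <- rbind(fake_candidate("S0001", "chr1", 5000, 2000),
               fake_candidate("S0002", "chr1", 10000, 2000))
  expect_equal(nrow(unify_cohort_numts(two, ref)), 2)

  # chain A-B (900 bp) and B-C (900 bp) with A-C 1,800 bp: single linkage
  chain <- rbind(fake_candidate("S0001", "chr1", 5000, 2000, width = 10),
                 fake_candidate("S0002", "chr1", 5900, 2000, width = 10),
                 fake_candidate("S0003", "chr1", 6800, 2000, width = 10))
  expect_equal(nrow(unify_cohort_numts(chain, ref)), 1)

  # carrier-count conservation: every candidate assigned exactly once
  set.seed(3)
  rand <- do.call(rbind, lapply(1:30, function(i)
    fake_candidate(sprintf("S%04d", i %% 7 + 1), "chr1",
                   sample(90000, 1), sample(16000, 1))))
  coh_r <- unify_cohort_numts(rand, ref)
  expect_equal(sum(lengths(strsplit(coh_r$member_ids, ";"))), nrow(rand))

  # invariance to sample order
  coh_s <- unify_cohort_numts(rand[sample(nrow(rand)), ], ref)
  cols <- c("nuclear_contig", "nuclear_start", "mt_start", "n_carriers")
  expect_equal(coh_r[, cols], coh_s[, cols])
})

test_that("frequency classes are exact at the 0.1% and 1% boundaries", {
  ref <- unification_ref()
  mk_cohort <- function(n_carr) {
    cands <- do.call(rbind, lapply(seq_len(n_carr), function(i)
      fake_candidate(sprintf("S%04d", i), "chr1", 5000, 2000)))
    unify_cohort_numts(cands, ref)
  }
  n <- 10000
  co <- classify_frequency_and_known(mk_cohort(100), n)   # F = 1% exactly
  expect_equal(co$freq_class, "common")
  co <- classify_frequency_and_known(mk_cohort(99), n)    # just below 1%
  expect_equal(co$freq_class, "rare")
  co <- classify_frequency_and_known(mk_cohort(10), n)    # F = 0.1% exactly
  expect_equal(co$freq_class, "rare")
  co <- classify_frequency_and_known(mk_cohort(5), n)     # F = 0.05%
  expect_equal(co$freq_class, "ultra_rare")
})

test_that("known matching uses 500 bp flanks regardless of mt fragment;
           private means one family", {
  ref <- unification_ref()
  coh <- unify_cohort_numts(rbind(
    fake_candidate("S0001", "chr1", 5000, 2000),
    fake_candidate("S0002", "chr1", 5010, 2000)), ref)
  # known NUMT 400 bp upstream, different mt fragment: still known
  known <- interval_track(data.frame(contig = "chr1", start = 4500,
                                     end = 4600, label = "known"), "known")
  man <- data.frame(sample = c("S0001", "S0002"), role = "singleton",
                    family = c("F1", "F1"), pair = NA)
  out <- classify_frequency_and_known(coh, 100, known = known,
                                      manifest = man)
  expect_true(out$known)
  expect_true(out$private)

  man2 <- transform(man, family = c("F1", "F2"))
  out2 <- classify_frequency_and_known(coh, 100, known = known,
                                       manifest = man2)
  expect_false(out2$private)

  far_known <- interval_track(data.frame(contig = "chr1", start = 900,
                                         end = 1000), "known")
  out3 <- classify_frequency_and_known(coh, 100, known = far_known)
  expect_false(out3$known)

  man_bad <- man[1, , drop = FALSE]
  expect_error(classify_frequency_and_known(coh, 100, manifest = man_bad),
               "missing a carrier")
})

test_that("cohort summaries: exact counts, rank-sum ties and correlation", {
  ref <- unification_ref()
  samples <- sprintf("S%04d", 1:5)
  # every sample carries exactly 4 NUMTs
  cands <- do.call(rbind, lapply(1:4, function(k)
    do.call(rbind, lapply(samples, function(s)
      fake_candidate(s, "chr1", 5000 + k * 8000, 1000 + k * 900)))))
  coh <- classify_frequency_and_known(unify_cohort_numts(cands, ref), 5)
  sm <- cohort_summaries(coh, samples)
  expect_equal(sm$mean_numts, 4)
  expect_equal(sm$sd_numts, 0)
  expect_true(is.na(sm$size_frequency$r))   # all sizes/frequencies equal

  rs <- ranksum_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(rs$p, 1)

  expect_true(is.na(cohort_summaries(coh[1:2, ], samples)$size_frequency$r))
})

test_that("planted negative size-frequency dependence is recovered", {
  # generative model on the cohort table: bigger NUMTs are rarer
  signs <- vapply(1:20, function(seed) {
    set.seed(seed)
    size <- runif(40, 100, 2000)
    f <- plogis(2 - 0.002 * size + rnorm(40, 0, 0.3)) * 0.2
    coh <- data.frame(size_bp = size, F = f, carriers = "S0001")
    sign(cohort_summaries(coh, "S0001")$size_frequency$r)
  }, 0)
  expect_true(all(signs < 0))
})
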