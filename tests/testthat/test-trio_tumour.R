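# De novo / tumour-specific calling rules, exact binomial rates, 2x2 tests.

fake_cand <- function(sample, start, support, contig = "chr1",
                      mt_start = 2000L) {
  data.frame(sample_id = sample, nuclear_contig = contig,
             nuclear_start = start, nuclear_end = start + 200L,
             mt_start = mt_start, mt_end = mt_start + 400L,
             support = support, orientation = "+/-",
             candidate_id = sprintf("%s:%d", sample, start))
}

trio_manifest <- function() {
  data.frame(sample = c("C1", "F1", "M1"),
             role = c("child", "father", "mother"),
             family = "FAM1", pair = NA)
}

trio_ref <- function()
  build_toy_references(c(chr1 = 50000), mt_length = 16569, seed = 1,
                       mt_mode = "random")

test_that("de novo calls require child support 5+ and parental absence", {
  ref <- trio_ref()
  man <- trio_manifest()
  run <- function(child_sup, father, mother) {
    cands <- list(C1 = fake_cand("C1", 5000, child_sup),
                  F1 = father, M1 = mother)
    call_de_novo(cands, man, ref)
  }
  none <- fake_cand("F1", 99999L, 1L)[0, ]
  # child 6 pairs, parents clean -> de novo
  expect_equal(nrow(run(6L, none, none)), 1)
  # father with 2 pairs at the locus vetoes (sensitivity re-check)
  expect_equal(nrow(run(6L, fake_cand("F1", 5050, 2L), none)), 0)
  # a single stray parental pair does not veto
  expect_equal(nrow(run(6L, fake_cand("F1", 5050, 1L), none)), 1)
  # mother carrying at high support vetoes
  expect_equal(nrow(run(8L, none, fake_cand("M1", 5000, 10L))), 0)
  # child below threshold: not de novo
  expect_equal(nrow(run(4L, none, none)), 0)
  # parental call at an unrelated locus does not veto
  expect_equal(nrow(run(6L, fake_cand("F1", 40000, 10L), none)), 1)
  # incomplete trio is skipped with a warning
  expect_warning(
    out <- call_de_novo(list(C1 = fake_cand("C1", 5000, 6L)), man, ref),
    "incomplete")
  expect_equal(attr(out, "n_incomplete"), 1L)
})

test_that("tumour-specific and lost NUMTs follow the support rules", {
  ref <- trio_ref()
  pairs <- list(c("T1", "N1"))
  run <- function(tumour, normal) {
    call_tumour_specific(list(T1 = tumour, N1 = normal), pairs, ref)
  }
  none <- fake_cand("x", 1L, 1L)[0, ]
  # tumour 7 / normal 0 -> tumour-specific
  out <- run(fake_cand("T1", 5000, 7L), none)
  expect_equal(nrow(out$tumour_specific), 1)
  expect_equal(nrow(out$lost), 0)
  # normal 6 / tumour 1 -> lost
  out <- run(fake_cand("T1", 5000, 1L), fake_cand("N1", 5000, 6L))
  expect_equal(nrow(out$lost), 1)
  expect_equal(nrow(out$tumour_specific), 0)
  # tumour 7 / normal 1 -> neither
  out <- run(fake_cand("T1", 5000, 7L), fake_cand("N1", 5000, 1L))
  expect_equal(nrow(out$tumour_specific), 0)
  expect_equal(nrow(out$lost), 0)
  # strict mode: presence in a non-cancer genome vetoes
  strict <- call_tumour_specific(
    list(T1 = fake_cand("T1", 5000, 7L), N1 = none,
         B1 = fake_cand("B1", 5000, 3L)),
    pairs, ref, strict = TRUE)
  expect_equal(nrow(strict$tumour_specific), 0)
  expect_error(call_tumour_specific(list(T1 = none), pairs, ref),
               "unmatched pair")
})

test_that("insertion rates use the exact Clopper-Pearson interval", {
  # closed-form sanity at the boundaries
  r0 <- insertion_rate(0, 100)
  expect_equal(r0$rho, 0)
  expect_equal(r0$ci_low, 0)
  r11 <- insertion_rate(1, 1)
  expect_equal(r11$ci_low, 0.025)        # (alpha/2)^(1/n) at events = n
  expect_equal(r11$ci_high, 1)
  # agreement with the independent exact binomial test across a grid
  for (x in c(0, 1, 2, 5, 20)) {
    bt <- binom.test(x, 200)
    cp <- insertion_rate(x, 200)
    expect_equal(cp$ci_low, bt$conf.int[1], tolerance = 1e-10)
    expect_equal(cp$ci_high, bt$conf.int[2], tolerance = 1e-10)
  }
  # rho monotone in events for fixed denominator
  rhos <- vapply(0:10, function(x) insertion_rate(x, 50)$rho, 0)
  expect_true(all(diff(rhos) > 0))
  expect_error(insertion_rate(2, 0), "denominator")
  expect_error(insertion_rate(5, 3), "events")
})

test_that("Clopper-Pearson coverage holds at the cohort's scale", {
  # 2,000 binomial draws at p = 0.001, n = 8,201: the exact interval
  # must cover p in at least 95% of runs (within 1.5 points)
  set.seed(20)
  p <- 0.001; n <- 8201
  x <- rbinom(2000, n, p)
  covered <- vapply(x, function(xi) {
    ci <- insertion_rate(xi, n)
    ci$ci_low <= p && p <= ci$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.95 - 0.015)
})

test_that("2x2 association matches the exact enumeration oracle", {
  sym <- two_by_two_association(10, 90, 10, 90)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$fisher_p, 1)

  # brute-force hypergeometric enumeration for the probability-mass rule
  tab <- c(a = 1, b = 9, c = 9, d = 1)
  m <- tab["a"] + tab["b"]; k <- tab["a"] + tab["c"]; N <- sum(tab)
  probs <- vapply(max(0, k + m - N):min(m, k), function(a)
    dhyper(a, m, N - m, k), 0)
  p_obs <- dhyper(tab["a"], m, N - m, k)
  p_oracle <- sum(probs[probs <= p_obs + 1e-12])
  got <- two_by_two_association(1, 9, 9, 1)
  expect_equal(got$fisher_p, unname(p_oracle), tolerance = 1e-10)

  zero <- two_by_two_association(0, 10, 5, 5)
  expect_true(zero$continuity)
  expect_gt(zero$odds_ratio, 0)
  expect_error(two_by_two_association(0, 0, 5, 5), "margins")
})

test_that("simulated trios separate de novo from inherited insertions", {
  ref <- build_toy_references(c(chr1 = 40000), seed = 14)
  des <- cohort_design(n_samples = 6,
                       trios = list(c("S0001", "S0002", "S0003"),
                                    c("S0004", "S0005", "S0006")),
                       seed = 77)
  numts <- list(
    simulated_numt("dn1", "chr1", 8000,
                   data.frame(mt_start = 3000, mt_end = 3499,
                              orientation = "+"),
                   carriers = "S0001", is_de_novo = TRUE),
    simulated_numt("inh1", "chr1", 20000,
                   data.frame(mt_start = 7000, mt_end = 7499,
                              orientation = "+"),
                   carriers = c("S0004", "S0005"))     # child + father
  )
  pl <- plant_numts(ref, numts, des)
  rd <- simulate_cohort_reads(pl)
  cands <- lapply(rd, function(r) detect_numts(r, pl$reference,
                                               min_support = 1))
  man <- design_manifest(des)
  dn <- call_de_novo(cands, man, pl$reference, reads_by_sample = rd)
  expect_equal(nrow(dn), 1)
  expect_equal(dn$sample_id, "S0001")
  expect_equal(dn$family, "F0001")
})
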