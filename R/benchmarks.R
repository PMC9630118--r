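# Validation experiments on synthetic cohorts. Each benchmark generates a
# cohort with planted ground truth under the stated study conditions, runs
# the pipeline, and reports the comparison against truth. The analysis
# scripts and the acceptance machinery are thin wrappers over these.

# match a call (nuclear span + mt span) against a truth record at the
# standard 1 kb distance on both genomes
.matches_truth <- function(cand, truth_row, mt_len, dist = 1000L) {
  if (cand$nuclear_contig != truth_row$nuclear_contig) return(FALSE)
  if (abs(cand$nuclear_start - truth_row$nuclear_pos) > dist &&
      abs(cand$nuclear_end - truth_row$nuclear_pos) > dist) return(FALSE)
  tspan <- normalize_mt_interval(truth_row$mt_start,
                                 if (truth_row$mt_end >= 1) truth_row$mt_end
                                 else mt_len, mt_len)
  s0 <- tspan$segments$start[1] - 1L
  e0 <- tspan$segments$end[nrow(tspan$segments)]
  .circular_span_gap(cand$mt_start, cand$mt_end, s0, e0, mt_len) <= dist
}

#' Detection benchmark on a simulated cohort
#'
#' Plants NUMTs of the study's size spectrum in a multi-sample cohort,
#' runs per-sample detection at the sensitive threshold and breakpoint
#' refinement, and scores recall, precision and breakpoint exactness
#' against truth.
#'
#' @param seed master seed.
#' @param n_samples cohort size (default 20).
#' @param depth mean coverage (default 30).
#' @param n_numts planted NUMTs (default 10).
#' @param size_range NUMT size range in bp (default 100-2,000).
#' @param min_support detection threshold (default 2).
#' @return list: `recall`, `precision`, `blunt_exact_fraction` (fraction of
#'   evaluated blunt junctions whose nuclear and mt positions equal truth
#'   exactly), `n_truth`, `n_calls`, plus the underlying tables.
#' @export
benchmark_detection <- function(seed = 1, n_samples = 20, depth = 30,
                                n_numts = 10, size_range = c(100, 2000),
                                min_support = 2) {
  ref <- build_toy_references(c(chr1 = 60000, chr2 = 40000),
                              seed = seed + 1000L)
  des <- cohort_design(n_samples = n_samples, mean_depth = depth,
                       seed = seed)
  .with_seed(seed + 1L, {
    carriers_list <- lapply(seq_len(n_numts), function(i)
      sample(des$sample_ids, sample(2:4, 1)))
  })
  numts <- sample_numts(ref, des, n_numts, size_range = size_range,
                        carriers_list = carriers_list, seed = seed + 2L)
  planted <- plant_numts(ref, numts, des)
  reads <- simulate_cohort_reads(planted)
  truth <- planted$truth
  mt_len <- planted$reference$mt_length

  calls <- list(); n_matched_truth <- 0L; n_calls <- 0L; n_good_calls <- 0L
  blunt_total <- 0L; blunt_exact <- 0L
  for (sid in des$sample_ids) {
    cand <- detect_numts(reads[[sid]], planted$reference,
                         min_support = min_support)
    calls[[sid]] <- cand
    tr_s <- truth[truth$sample_id == sid, , drop = FALSE]
    n_calls <- n_calls + nrow(cand)
    for (i in seq_len(nrow(cand))) {
      hit <- any(vapply(seq_len(nrow(tr_s)), function(k)
        .matches_truth(cand[i, ], tr_s[k, ], mt_len), logical(1)))
      n_good_calls <- n_good_calls + hit
    }
    for (k in seq_len(nrow(tr_s))) {
      hit <- any(vapply(seq_len(nrow(cand)), function(i)
        .matches_truth(cand[i, ], tr_s[k, ], mt_len), logical(1)))
      n_matched_truth <- n_matched_truth + hit
    }
    # breakpoint exactness for blunt planted junctions
    bp <- refine_breakpoints(reads[[sid]], cand, planted$reference)
    jc <- bp$junction_classes
    if (is.null(jc)) jc <- data.frame(nuclear_bp = integer(0))
    for (k in seq_len(nrow(tr_s))) {
      tr <- tr_s[k, ]
      if (tr$mh_len > 0 || nzchar(tr$inserted_bases)) next
      mine <- jc[abs(jc$nuclear_bp - tr$nuclear_pos) <= 1000, ,
                 drop = FALSE]
      if (nrow(mine) == 0) next
      for (j in seq_len(nrow(mine))) {
        blunt_total <- blunt_total + 1L
        expected_mt <- if (mine$junction[j] == "left") tr$mt_start
                       else tr$mt_end
        blunt_exact <- blunt_exact +
          (mine$nuclear_bp[j] == tr$nuclear_pos &&
             mine$mt_bp[j] == expected_mt)
      }
    }
  }
  list(recall = n_matched_truth / nrow(truth),
       precision = if (n_calls > 0) n_good_calls / n_calls else NA_real_,
       blunt_exact_fraction = if (blunt_total > 0)
         blunt_exact / blunt_total else NA_real_,
       n_truth = nrow(truth), n_calls = n_calls,
       truth = truth, calls = calls, reference = planted$reference)
}

#' Trio de novo calling benchmark
#'
#' Simulates trios with planted child-only (de novo) and inherited
#' insertions, and scores de novo recall and false calls.
#'
#' @param seed master seed.
#' @param n_trios number of trios (default 50).
#' @param n_de_novo child-only events (default 5, one per distinct child).
#' @param n_inherited child+father events (default 5).
#' @param depth mean coverage.
#' @return list: `n_de_novo_true`, `n_recovered`, `n_false`, `rate`
#'   (a [insertion_rate()] estimate of recovered events per trio).
#' @export
benchmark_trios <- function(seed = 1, n_trios = 50, n_de_novo = 5,
                            n_inherited = 5, depth = 30) {
  n_samples <- 3 * n_trios
  ids <- sprintf("S%04d", seq_len(n_samples))
  trios <- lapply(seq_len(n_trios), function(i)
    ids[(3 * i - 2):(3 * i)])            # child, father, mother
  ref <- build_toy_references(c(chr1 = 30000), seed = seed + 1000L)
  des <- cohort_design(n_samples, trios = trios, mean_depth = depth,
                       seed = seed, sample_ids = ids)
  carriers <- c(
    lapply(seq_len(n_de_novo), function(i) trios[[i]][1]),
    lapply(seq_len(n_inherited), function(i)
      trios[[n_de_novo + i]][c(1, 2)])
  )
  numts <- sample_numts(ref, des, n_de_novo + n_inherited,
                        size_range = c(200, 800),
                        carriers_list = carriers, seed = seed + 2L)
  for (i in seq_len(n_de_novo)) numts[[i]]$is_de_novo <- TRUE
  planted <- plant_numts(ref, numts, des)
  reads <- simulate_cohort_reads(planted)
  cands <- lapply(reads, function(r)
    detect_numts(r, planted$reference, min_support = 1))
  man <- design_manifest(des)
  dn <- call_de_novo(cands, man, planted$reference,
                     reads_by_sample = reads)
  truth <- planted$truth
  dn_truth <- truth[truth$is_de_novo, , drop = FALSE]
  mt_len <- planted$reference$mt_length
  recovered <- 0L
  for (k in seq_len(nrow(dn_truth))) {
    hit <- any(vapply(seq_len(nrow(dn)), function(i)
      dn$sample_id[i] == dn_truth$sample_id[k] &&
        .matches_truth(dn[i, ], dn_truth[k, ], mt_len), logical(1)))
    recovered <- recovered + hit
  }
  false_calls <- 0L
  for (i in seq_len(nrow(dn))) {
    hit <- any(vapply(seq_len(nrow(dn_truth)), function(k)
      dn$sample_id[i] == dn_truth$sample_id[k] &&
        .matches_truth(dn[i, ], dn_truth[k, ], mt_len), logical(1)))
    false_calls <- false_calls + !hit
  }
  list(n_de_novo_true = nrow(dn_truth), n_recovered = recovered,
       n_false = false_calls,
       rate = insertion_rate(recovered, n_trios))
}

#' Concatenated-NUMT recovery benchmark
#'
#' Plants a two-segment NUMT with a known internal mtDNA-mtDNA junction
#' plus two decoys (a deletion-like sub-50 bp junction and a D-loop
#' terminus junction) and checks the filter cascade.
#'
#' @param seed master seed.
#' @return list: `junction_error_bp` (max |called - truth| over the two
#'   positions), `n_junctions`, `decoys_removed`.
#' @export
benchmark_concatenation <- function(seed = 1) {
  ref <- build_toy_references(c(chr1 = 40000), seed = seed + 1000L)
  des <- cohort_design(n_samples = 5, seed = seed)
  numts <- list(
    simulated_numt("real", "chr1", 9000,
                   data.frame(mt_start = c(12000, 14977),
                              mt_end = c(12867, 15500),
                              orientation = c("+", "+")),
                   carriers = c("S0001", "S0002")),
    simulated_numt("del_decoy", "chr1", 20000,
                   data.frame(mt_start = c(7000, 7530),
                              mt_end = c(7500, 8000),
                              orientation = c("+", "+")),
                   carriers = "S0004"),
    simulated_numt("term_decoy", "chr1", 30000,
                   data.frame(mt_start = c(16300, 3000),
                              mt_end = c(16520, 3400),
                              orientation = c("+", "+")),
                   carriers = "S0005")
  )
  planted <- plant_numts(ref, numts, des)
  reads <- simulate_cohort_reads(planted)
  jx <- detect_mt_mt_junctions(reads, planted$reference)
  err <- if (nrow(jx) >= 1)
    max(abs(jx$pos1[1] - 12867), abs(jx$pos2[1] - 14977)) else NA_real_
  list(junction_error_bp = err, n_junctions = nrow(jx),
       decoys_removed = nrow(jx) == 1)
}

#' Permutation-test calibration benchmark
#'
#' Runs many enrichment tests of uniformly placed positions against a
#' fixed annotation track and reports the fraction reaching p < 0.05,
#' which should sit near the nominal level under the null.
#'
#' @param seed master seed.
#' @param n_tests number of null tests (default 400).
#' @param n_perm permutation replicates per test (default 1,000).
#' @param n_positions positions per test (default 200; a fine-grained
#'   count statistic keeps the discrete two-tailed p close to nominal, as
#'   at cohort scale, whereas very small position sets make it
#'   conservative).
#' @return list: `fraction_significant`, `n_tests`.
#' @export
benchmark_permutation_calibration <- function(seed = 1, n_tests = 400,
                                              n_perm = 1000,
                                              n_positions = 200) {
  ref <- build_toy_references(c(chr1 = 100000, chr2 = 80000),
                              seed = seed + 1000L)
  iv <- do.call(rbind, lapply(c("chr1", "chr2"), function(cc) {
    L <- nchar(ref_seq(ref, cc))
    s <- seq(0, L - 10000, by = 10000)
    data.frame(contig = cc, start = s, end = s + 1000)
  }))
  track <- interval_track(iv, "calibration")
  ps <- .with_seed(seed, {
    vapply(seq_len(n_tests), function(t) {
      pos <- data.frame(contig = sample(c("chr1", "chr2"), n_positions,
                                        replace = TRUE),
                        pos = sample(70000L, n_positions, replace = TRUE))
      permutation_enrichment(pos, track, ref, n_perm = n_perm,
                             seed = seed * 100000L + t)$empirical_p
    }, 0)
  })
  list(fraction_significant = mean(ps < 0.05), n_tests = n_tests)
}

#' NUMT age-recovery benchmark
#'
#' Plants NUMTs with a known ancestral-allele fraction (age_fraction) and
#' compares the estimated ages against the planted value
#' age = age_fraction x 6 Myr, over fragments with at least
#' `min_informative` informative sites.
#'
#' @param seed master seed.
#' @param n_numts planted NUMTs (default 50).
#' @param age_fraction planted ancestral fraction (default 0.25, i.e.
#'   1.5 Myr).
#' @param depth mean coverage (default 15; consensus assembly needs
#'   modest tiling only).
#' @param min_informative informative-site floor for scoring (default 20).
#' @return list: `mean_age`, `true_age`, `mean_abs_error` (|mean - truth|),
#'   `n_scored`, `ages` (per-NUMT table).
#' @export
benchmark_age_recovery <- function(seed = 1, n_numts = 50,
                                   age_fraction = 0.25, depth = 15,
                                   min_informative = 20) {
  ref <- build_toy_references(c(chr1 = 120000, chr2 = 120000),
                              seed = seed + 1000L)
  des <- cohort_design(n_samples = 16, mean_depth = depth, seed = seed)
  chimp <- synthetic_chimp_mt(ref_seq(ref, "MT"))
  placeholder <- lapply(seq_len(n_numts), function(i) des$sample_ids[1])
  numts <- sample_numts(ref, des, n_numts, size_range = c(450, 950),
                        carriers_list = placeholder,
                        age_fraction = age_fraction, seed = seed + 2L)
  # carriers are assigned so that no sample carries two NUMTs with
  # overlapping mt fragments: reads from paralogous fragments would
  # otherwise contaminate each other's consensus
  L <- ref$mt_length
  spans <- lapply(numts, function(nu) {
    s <- nu$segments$mt_start[1]; e <- nu$segments$mt_end[1]
    if (e < s) e <- e + L
    c(s, e)
  })
  occupied <- setNames(vector("list", des$n_samples), des$sample_ids)
  overlaps <- function(a, b) {
    for (sh in c(-L, 0, L)) if (a[1] < b[2] + sh + 100 &&
                                b[1] + sh < a[2] + 100) return(TRUE)
    FALSE
  }
  .with_seed(seed + 1L, {
    for (i in seq_len(n_numts)) {
      free <- Filter(function(sid)
        !any(vapply(occupied[[sid]], function(b)
          overlaps(spans[[i]], b), logical(1))),
        des$sample_ids)
      load <- vapply(free, function(sid) length(occupied[[sid]]), 0L)
      pick <- free[order(load, runif(length(free)))][1:2]
      numts[[i]]$carriers <- pick
      for (sid in pick)
        occupied[[sid]] <- c(occupied[[sid]], list(spans[[i]]))
    }
  })
  planted <- plant_numts(ref, numts, des, chimp_mt = chimp)
  reads <- simulate_cohort_reads(planted)
  cands <- lapply(reads, function(r)
    detect_numts(r, planted$reference, min_support = 2))
  cohort <- classify_frequency_and_known(
    unify_cohort_numts(do.call(rbind, cands), planted$reference),
    n_samples = des$n_samples)
  cons <- assemble_cohort_consensus(reads, cohort, planted$reference)
  ages <- estimate_numt_age(cons, cohort, planted$reference,
                            chimp_mt = chimp)
  scored <- ages[ages$n_informative >= min_informative, , drop = FALSE]
  true_age <- age_fraction * 6
  list(mean_age = mean(scored$age_myr), true_age = true_age,
       mean_abs_error = abs(mean(scored$age_myr) - true_age),
       n_scored = nrow(scored), ages = ages)
}

#' Variant-group integrity benchmark
#'
#' Runs the variant cascade on (a) a cohort with planted subset-carrier
#' variants, checking group containment C within B within A, and (b) a
#' clean cohort with no planted variants, checking that zero variants are
#' called.
#'
#' @param seed master seed.
#' @return list: `containment_ok`, `n_false_variants`, `groups`
#'   (the classified variant table).
#' @export
benchmark_variant_groups <- function(seed = 1) {
  ref <- build_toy_references(c(chr1 = 60000), seed = seed + 1000L)
  des <- cohort_design(n_samples = 6,
                       trios = list(c("S0001", "S0002", "S0006")),
                       seed = seed)
  mt <- ref_seq(ref, "MT")
  alt_of <- function(p) setdiff(BASES, substr(mt, p, p))[1]
  numts <- list(
    simulated_numt("v1", "chr1", 10000,
                   data.frame(mt_start = 3000, mt_end = 3599,
                              orientation = "+"),
                   carriers = sprintf("S%04d", 1:5),
                   planted_variants = data.frame(
                     mt_pos = c(3300, 3400, 3500),
                     alt = c(alt_of(3300), alt_of(3400), alt_of(3500)),
                     carriers = c("S0001;S0002", "S0003", NA))),
    simulated_numt("clean", "chr1", 40000,
                   data.frame(mt_start = 8000, mt_end = 8399,
                              orientation = "+"),
                   carriers = c("S0004", "S0005"))
  )
  planted <- plant_numts(ref, numts, des)
  reads <- simulate_cohort_reads(planted)
  cands <- lapply(reads, function(r)
    detect_numts(r, planted$reference, min_support = 2))
  cohort <- classify_frequency_and_known(
    unify_cohort_numts(do.call(rbind, cands), planted$reference),
    n_samples = 6, manifest = design_manifest(des))
  cons <- assemble_cohort_consensus(reads, cohort, planted$reference)
  v <- call_numt_variants(cons, cohort, planted$reference)
  g <- classify_variant_groups(v, cohort, design_manifest(des))
  containment <- all(!g$in_C | g$in_B) && all(!g$in_B | g$in_A)
  clean_id <- cohort$cohort_numt_id[cohort$nuclear_start > 30000]
  false_v <- sum(g$cohort_numt_id %in% clean_id)
  list(containment_ok = containment, n_false_variants = false_v,
       groups = g)
}
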