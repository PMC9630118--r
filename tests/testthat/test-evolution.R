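# Consensus assembly, NUMT-variant cascade, variant groups, coding effects,
# mutational spectra and ancestral-ratio ages.

test_that("greedy overlap assembly reconstructs an error-free template", {
  set.seed(6)
  template <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  starts <- seq(1, 301, by = 20)
  reads <- vapply(starts, function(s) substr(template, s, s + 99),
                  character(1))
  asm <- assemble_numt_consensus(reads)
  expect_false(asm$fragmented)
  expect_equal(asm$consensus, template)

  # two reads with no overlap: fragmented, longest contig returned
  asm2 <- assemble_numt_consensus(c(substr(template, 1, 80),
                                    substr(template, 300, 400)))
  expect_true(asm2$fragmented)
  expect_equal(asm2$consensus, substr(template, 300, 400))
})

test_that("column majority keeps the majority allele; exact ties go to the
           reference", {
  set.seed(9)
  template <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  alt_base <- setdiff(c("A", "C", "G", "T"), substr(template, 150, 150))[1]
  alt <- template
  substr(alt, 150, 150) <- alt_base
  tile <- function(tmpl, starts) vapply(starts, function(s)
    substr(tmpl, s, s + 99), character(1))
  # 2/3 of reads covering position 150 carry the variant
  reads <- c(tile(alt, c(60, 80, 100, 120, 140)),
             tile(template, c(70, 110)),
             tile(template, c(1, 20, 40, 160, 180, 200)))
  asm <- assemble_numt_consensus(reads, ref_fragment = template)
  expect_equal(substr(asm$consensus, 150, 150), alt_base)

  # exact 50-50 tie resolves to the reference base
  reads_tie <- c(tile(alt, c(60, 100)), tile(template, c(80, 120)),
                 tile(template, c(1, 30, 160, 200)))
  asm_tie <- assemble_numt_consensus(reads_tie, ref_fragment = template)
  expect_equal(substr(asm_tie$consensus, 150, 150),
               substr(template, 150, 150))
})

evo_fixture <- function(seed = 9) {
  ref <- build_toy_references(c(chr1 = 60000), seed = 3)
  des <- cohort_design(n_samples = 6,
                       trios = list(c("S0001", "S0002", "S0006")),
                       seed = seed)
  chimp <- synthetic_chimp_mt(ref_seq(ref, "MT"))
  mt <- ref_seq(ref, "MT")
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"),
                                substr(mt, p, p))[1]
  numts <- list(
    simulated_numt("v1", "chr1", 10000,
                   data.frame(mt_start = 3000, mt_end = 3599,
                              orientation = "+"),
                   carriers = c("S0001", "S0002", "S0003", "S0004",
                                "S0005"),
                   planted_variants = data.frame(
                     mt_pos = c(3300, 3400, 3500),
                     alt = c(alt_of(3300), alt_of(3400), alt_of(3500)),
                     carriers = c("S0001;S0002", "S0003", NA))),
    simulated_numt("v2", "chr1", 40000,
                   data.frame(mt_start = 8000, mt_end = 8399,
                              orientation = "+"),
                   carriers = c("S0004", "S0005"))
  )
  planted <- plant_numts(ref, numts, des, chimp_mt = chimp)
  reads <- simulate_cohort_reads(planted)
  cands <- lapply(reads, function(r) detect_numts(r, planted$reference,
                                                  min_support = 2))
  cohort <- classify_frequency_and_known(
    unify_cohort_numts(do.call(rbind, cands), planted$reference),
    n_samples = 6, manifest = design_manifest(des))
  cons <- assemble_cohort_consensus(reads, cohort, planted$reference)
  list(planted = planted, des = des, chimp = chimp, cohort = cohort,
       cons = cons)
}

# built once for the file: the fixture drives three test blocks
fx_shared <- evo_fixture()

test_that("the variant filter cascade recovers planted variants and the
           group classification is nested", {
  fx <- fx_shared
  v <- call_numt_variants(fx$cons, fx$cohort, fx$planted$reference)
  # the three planted variants are recovered with exact carrier counts
  planted_pos <- c(3300, 3400, 3500)
  got <- v[v$mt_pos %in% planted_pos, ]
  expect_equal(sort(got$mt_pos), planted_pos)
  expect_equal(got$carrier_count[order(got$mt_pos)], c(2L, 1L, 5L))

  g <- classify_variant_groups(v, fx$cohort, design_manifest(fx$des))
  # full-carrier variant is not NUMT-specific (likely predates insertion)
  expect_false(g$numt_specific[g$mt_pos == 3500])
  # family pair (child + father) reaches subgroup C
  expect_equal(g$group[g$mt_pos == 3300], "C")
  expect_equal(g$group[g$mt_pos == 3400], "A")
  # containment C subset of B subset of A
  expect_true(all(!g$in_C | g$in_B))
  expect_true(all(!g$in_B | g$in_A))
})

test_that("clean simulations produce zero variants (specificity)", {
  ref <- build_toy_references(c(chr1 = 40000), seed = 31)
  des <- cohort_design(n_samples = 2, seed = 8)
  nu <- simulated_numt("z", "chr1", 9000,
                       data.frame(mt_start = 6000, mt_end = 6599,
                                  orientation = "+"),
                       carriers = c("S0001", "S0002"))
  pl <- plant_numts(ref, list(nu), des)
  rd <- simulate_cohort_reads(pl)
  cands <- lapply(rd, function(r) detect_numts(r, pl$reference,
                                               min_support = 2))
  coh <- classify_frequency_and_known(
    unify_cohort_numts(do.call(rbind, cands), pl$reference), 2)
  cons <- assemble_cohort_consensus(rd, coh, pl$reference)
  v <- call_numt_variants(cons, coh, pl$reference)
  expect_equal(nrow(v), 0)
})

test_that("cascade details: size cap, breakpoint margin, low complexity", {
  ref <- build_toy_references(c(chr1 = 30000), seed = 2)
  cohort <- data.frame(cohort_numt_id = c("big", "small"),
                       nuclear_contig = "chr1", nuclear_start = 1000L,
                       nuclear_end = 1000L,
                       mt_start = c(1999L, 299L), mt_end = c(3499L, 599L),
                       size_bp = c(1500L, 300L), carriers = "S0001",
                       n_carriers = 1L, freq_class = "ultra_rare")
  mt <- ref_seq(ref, "MT")
  frag_small <- substr(mt, 300, 599)
  # variant 3 bp from the 5' breakpoint and one inside low-complexity
  # region 300-316; one clean variant at offset 150
  mut <- function(s, at) {
    b <- substr(s, at, at)
    substr(s, at, at) <- setdiff(c("A", "C", "G", "T"), b)[1]
    s
  }
  cons_seq <- mut(mut(mut(frag_small, 3), 11), 150)
  cons <- data.frame(cohort_numt_id = "small", sample_id = "S0001",
                     consensus = cons_seq)
  v <- call_numt_variants(cons, cohort, ref)
  # only the clean variant survives: mt 302 (margin), mt 310
  # (low-complexity) are removed
  expect_equal(v$mt_pos, 449L)

  # NUMTs at or above 1,000 bp contribute no variants
  cons_big <- data.frame(cohort_numt_id = "big", sample_id = "S0001",
                         consensus = mut(substr(mt, 2000, 3499), 700))
  expect_equal(nrow(call_numt_variants(cons_big, cohort, ref)), 0)
})

test_that("coding effects use the vertebrate mitochondrial code and the
           96-class spectrum is pyrimidine-centred", {
  # toy mt genome with a plus-strand gene at 101..160 starting ATA
  mt <- paste0(strrep("T", 98), "CA", "ATA", "CCT",
               strrep("GCT", 18), strrep("A", 1300))
  ref <- string_reference(strrep("A", 2000), mt)
  regions <- data.frame(region = c("D-loop", "HV1", "HV2", "HV3", "OH",
                                   "OL", "toygene"),
                        start = c(1, 1, 2, 3, 4, 5, 101),
                        end = c(50, 10, 11, 12, 13, 14, 160),
                        strand = c(rep("+", 6), "+"),
                        type = c(rep("control", 5), "origin", "protein"))
  # ATA -> ATG at mt 103: Met -> Met, synonymous under code table 2
  v <- data.frame(mt_pos = 103L, ref = "A", alt = "G")
  ce <- coding_effect_and_spectrum(v, ref, regions = regions)
  expect_equal(ce$effects$effect, "synonymous")
  # ATA -> ACA would be Met -> Thr: non-synonymous
  v2 <- data.frame(mt_pos = 102L, ref = "T", alt = "C")
  ce2 <- coding_effect_and_spectrum(v2, ref, regions = regions)
  expect_equal(ce2$effects$effect, "non_synonymous")

  # C>T in an ACA context counts in class A[C>T]A
  mt2 <- paste0(strrep("G", 99), "ACA", strrep("G", 898))
  ref2 <- string_reference(strrep("A", 2000), mt2)
  v3 <- data.frame(mt_pos = 101L, ref = "C", alt = "T")
  ce3 <- coding_effect_and_spectrum(v3, ref2, regions = regions)
  expect_equal(unname(ce3$spectrum["A[C>T]A"]), 1)
  expect_equal(sum(ce3$spectrum), 1)

  # purine reference is reverse-complemented: G>A in TGG -> C[C>T]A
  mt3 <- paste0(strrep("C", 99), "TGG", strrep("C", 898))
  ref3 <- string_reference(strrep("A", 2000), mt3)
  v4 <- data.frame(mt_pos = 101L, ref = "G", alt = "A")
  ce4 <- coding_effect_and_spectrum(v4, ref3, regions = regions)
  expect_equal(unname(ce4$spectrum["C[C>T]A"]), 1)

  # cosine similarity against a matching one-hot signature
  sig <- matrix(0, 96, 2,
                dimnames = list(names(ce4$spectrum), c("match", "other")))
  sig["C[C>T]A", "match"] <- 1
  sig["T[T>A]T", "other"] <- 1
  cs <- coding_effect_and_spectrum(v4, ref3, regions = regions,
                                   signatures = sig)$cosine
  expect_equal(unname(cs["match"]), 1)
  expect_equal(unname(cs["other"]), 0)
})

test_that("age estimation follows (1 - r) * 6 and its filter cascade", {
  fx <- fx_shared
  # v2 planted with age_fraction 0: every informative site matches human
  age <- estimate_numt_age(fx$cons, fx$cohort, fx$planted$reference,
                           chimp_mt = fx$chimp)
  v2 <- fx$cohort$cohort_numt_id[fx$cohort$nuclear_start > 30000]
  row <- age[age$cohort_numt_id == v2, ]
  expect_equal(row$r, 1)
  expect_equal(row$age_myr, 0)
  # construction: r = 0.5 maps to 3 Myr
  expect_equal((1 - 0.5) * 6, 3)

  # concatenated NUMTs are excluded
  age2 <- estimate_numt_age(fx$cons, fx$cohort, fx$planted$reference,
                            chimp_mt = fx$chimp, concatenated_ids = v2)
  expect_false(v2 %in% age2$cohort_numt_id)

  # single-carrier NUMTs are excluded (filter 3)
  solo <- fx$cons[fx$cons$sample_id == "S0004" &
                    fx$cons$cohort_numt_id == v2, ]
  age3 <- estimate_numt_age(solo, fx$cohort, fx$planted$reference,
                            chimp_mt = fx$chimp)
  expect_equal(nrow(age3), 0)
})
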