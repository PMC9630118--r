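# Synthetic cohort generator: determinism, splice arithmetic, read-level
# junction signatures and the machine-readable truth set.

test_that("toy references are deterministic and validate configuration", {
  r1 <- build_toy_references(c(chr1 = 5000), mt_length = 2000,
                             seed = 1, mt_mode = "random")
  r2 <- build_toy_references(c(chr1 = 5000), mt_length = 2000,
                             seed = 1, mt_mode = "random")
  expect_identical(r1$contigs, r2$contigs)
  r3 <- build_toy_references(c(chr1 = 5000), mt_length = 2000,
                             seed = 2, mt_mode = "random")
  expect_false(identical(r1$contigs["chr1"], r3$contigs["chr1"]))

  fixed <- build_toy_references(c(chr1 = 5000), seed = 9)
  expect_equal(fixed$mt_length, 16569L)
  expect_identical(ref_seq(fixed, "MT"), synthetic_mt_genome())

  expect_error(build_toy_references(integer(0)), "configuration")
  expect_error(build_toy_references(c(chr1 = 5000), mt_length = 500,
                                    mt_mode = "random"), "configuration")
})

test_that("donor splice arithmetic conserves length per junction class", {
  ref <- build_toy_references(c(chr1 = 20000), seed = 4)
  des <- cohort_design(n_samples = 1, seed = 1)
  L0 <- nchar(ref_seq(ref, "chr1"))

  blunt <- simulated_numt("b", "chr1", 5000,
                          data.frame(mt_start = 1000, mt_end = 1299,
                                     orientation = "+"), carriers = "S0001")
  pl <- plant_numts(ref, list(blunt), des)
  expect_equal(nchar(pl$donors$S0001$chr1$seq), L0 + 300L)

  mh <- simulated_numt("m", "chr1", 5000,
                       data.frame(mt_start = 1100, mt_end = 1399,
                                  orientation = "+"), carriers = "S0001",
                       mh_len = 3)
  pl <- plant_numts(ref, list(mh), des)
  # shared bases are counted once
  expect_equal(nchar(pl$donors$S0001$chr1$seq), L0 + 300L - 3L)
  # the homology really is shared: nuclear flank end == insert start
  A <- ref_seq(pl$reference, "chr1"); M <- ref_seq(pl$reference, "MT")
  expect_equal(substr(A, 4998, 5000), substr(M, 1100, 1102))

  ins <- simulated_numt("i", "chr1", 5000,
                        data.frame(mt_start = 1000, mt_end = 1299,
                                   orientation = "+"), carriers = "S0001",
                        inserted_bases = "GT")
  pl <- plant_numts(ref, list(ins), des)
  expect_equal(nchar(pl$donors$S0001$chr1$seq), L0 + 302L)
})

test_that("planting validates overlap, edge distance and segment size", {
  ref <- build_toy_references(c(chr1 = 20000), seed = 4)
  des <- cohort_design(n_samples = 1, seed = 1)
  seg <- data.frame(mt_start = 1000, mt_end = 1299, orientation = "+")
  near_end <- simulated_numt("x", "chr1", 40, seg, carriers = "S0001")
  expect_error(plant_numts(ref, list(near_end), des), "contig end")
  tiny <- simulated_numt("x", "chr1", 5000,
                         data.frame(mt_start = 1000, mt_end = 1010,
                                    orientation = "+"), carriers = "S0001")
  expect_error(plant_numts(ref, list(tiny), des), "24 bp")
  a <- simulated_numt("a", "chr1", 5000, seg, carriers = "S0001")
  b <- simulated_numt("b", "chr1", 5100, seg, carriers = "S0001")
  expect_error(plant_numts(ref, list(a, b), des), "overlapping")
  expect_error(simulated_numt("x", "chr1", 5000, seg, carriers = "S0001",
                              mh_len = 2, inserted_bases = "AC"),
               "mutually exclusive")
})

test_that("simulation is a pure function of (design, seed)", {
  cb1 <- tiny_cohort(seed = 42)
  cb2 <- tiny_cohort(seed = 42)
  for (s in names(cb1$reads))
    expect_identical(cb1$reads[[s]], cb2$reads[[s]])
  # byte-identical SAM output
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(cb1$reads$S0001, cb1$reference, f1)
  write_sam(cb2$reads$S0001, cb2$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero depth yields a header-only SAM body", {
  ref <- build_toy_references(c(chr1 = 20000), seed = 4)
  des <- cohort_design(n_samples = 1, mean_depth = 0, seed = 1)
  nu <- simulated_numt("x", "chr1", 5000,
                       data.frame(mt_start = 1000, mt_end = 1299,
                                  orientation = "+"), carriers = "S0001")
  pl <- plant_numts(ref, list(nu), des)
  rd <- simulate_cohort_reads(pl)
  expect_equal(nrow(rd$S0001), 0)
  f <- tempfile()
  write_sam(rd$S0001, ref, f)
  expect_true(all(startsWith(readLines(f), "@")))
})

test_that("anchored discordant-pair counts match the coverage expectation", {
  # pairs whose mates are cleanly anchored on opposite sides of the insert:
  # expected ~ depth * (insert_mean - 2*read_length) / (2*read_length) at
  # each junction; checked within 3 sigma (Poisson) for a 500 bp NUMT
  ref <- build_toy_references(c(chr1 = 60000), seed = 8)
  des <- cohort_design(n_samples = 1, mean_depth = 30, seed = 3)
  nu <- simulated_numt("x", "chr1", 30000,
                       data.frame(mt_start = 4000, mt_end = 4499,
                                  orientation = "+"), carriers = "S0001")
  pl <- plant_numts(ref, list(nu), des)
  rd <- simulate_cohort_reads(pl)
  pairs <- extract_discordant_pairs(rd$S0001, pl$reference)
  # restrict to cleanly anchored pairs (no soft clips on either mate)
  ids <- pairs$read_id
  clipless <- vapply(ids, function(id) {
    recs <- rd$S0001[rd$S0001$read_id == id, ]
    all(!grepl("S", recs$cigar))
  }, logical(1))
  n_obs <- sum(clipless)
  lambda <- 2 * des$mean_depth *
    (des$insert_mean - 2 * des$read_length) / (2 * des$read_length)
  expect_lt(abs(n_obs - lambda), 3 * sqrt(lambda) + 1)
})

test_that("every planted junction yields split and discordant evidence", {
  cb <- tiny_cohort()
  truth <- cb$planted$truth
  for (i in seq_len(nrow(truth))) {
    r <- cb$reads[[truth$sample_id[i]]]
    pairs <- extract_discordant_pairs(r, cb$reference)
    near <- pairs$nuclear_contig == truth$nuclear_contig[i] &
      abs(pairs$nuclear_start - truth$nuclear_pos[i]) < 1000
    expect_gte(sum(near), 1)
    clipped <- grepl("S", r$cigar) & !is.na(r$contig) &
      r$contig == truth$nuclear_contig[i] &
      abs(r$start - truth$nuclear_pos[i]) < 1000
    expect_gte(sum(clipped), 1)
  }
})

test_that("decoy repeat regions silence alignments via MAPQ 0", {
  ref <- build_toy_references(c(chr1 = 20000), seed = 4)
  decoys <- interval_track(data.frame(contig = "chr1", start = 4000,
                                      end = 6000), "decoys")
  des <- cohort_design(n_samples = 1, seed = 1, decoys = decoys)
  nu <- simulated_numt("x", "chr1", 5000,
                       data.frame(mt_start = 1000, mt_end = 1299,
                                  orientation = "+"), carriers = "S0001")
  pl <- plant_numts(ref, list(nu), des)
  rd <- simulate_cohort_reads(pl)
  in_decoy <- !is.na(rd$S0001$contig) & rd$S0001$contig == "chr1" &
    rd$S0001$start >= 4000 & rd$S0001$start < 5900
  expect_true(all(rd$S0001$mapq[in_decoy] == 0))
  # consequence: no NUMT call survives the MAPQ filter
  expect_equal(nrow(detect_numts(rd$S0001, pl$reference, min_support = 2)), 0)
})

test_that("truth sets round-trip with exact carrier frequencies", {
  cb <- tiny_cohort()
  f <- tempfile(fileext = ".json")
  write_truth_set(cb$planted$truth, cb$design, f)
  back <- read_truth_set(f)
  expect_equal(back$parameters$seed, cb$design$seed)
  expect_equal(nrow(back$records), nrow(cb$planted$truth))
  expect_equal(back$records$numt_id, cb$planted$truth$numt_id)
  # realized carrier counts match the declaration exactly
  carriers <- table(cb$planted$truth$numt_id)
  expect_equal(as.integer(carriers[c("n1", "n2", "n3")]), c(2L, 1L, 1L))
})
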