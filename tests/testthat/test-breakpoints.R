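# Split-read collection, realignment, breakpoint definition and junction
# mechanism classification, plus breakpoint sequence context.

test_that("split-read collection applies clip and distance thresholds", {
  cb <- tiny_cohort()
  cand <- detect_numts(cb$reads$S0002, cb$reference, min_support = 2)[1, ]
  base <- collect_split_reads(cb$reads$S0002, cand, cb$reference)
  expect_gt(nrow(base), 0)
  clips <- t(vapply(base$cigar, cigar_clips, c(left = 0L, right = 0L)))
  expect_true(all(pmax(clips[, 1], clips[, 2]) >= 20))

  far <- cand; far$nuclear_start <- 45000L; far$nuclear_end <- 45100L
  far$mt_start <- 9000L; far$mt_end <- 9100L
  expect_equal(nrow(collect_split_reads(cb$reads$S0002, far, cb$reference)),
               0)

  # clip below min_clip is excluded
  small_clip <- make_read("sc", "chr1", cand$nuclear_start, "8S92M",
                          strrep("A", 100), sample_id = "S0002")
  expect_equal(nrow(collect_split_reads(small_clip, cand, cb$reference)), 0)
})

test_that("realignment recovers planted junction structure from truth", {
  cb <- tiny_cohort()
  truth <- cb$planted$truth
  A <- ref_seq(cb$reference, "chr1")
  M <- ref_seq(cb$reference, "MT")

  # blunt: segments meet exactly at truth coordinates, no overlap, no gap
  q_blunt <- paste0(substr(A, 9926, 10000), substr(M, 2000, 2074))
  cand <- data.frame(sample_id = "S0001", nuclear_contig = "chr1",
                     nuclear_start = 9700L, nuclear_end = 10300L,
                     mt_start = 1999L, mt_end = 2499L, support = 10L,
                     orientation = "x", candidate_id = "c")
  al <- realign_split_read(
    make_read("rb", "chr1", 9925, "75M75S", q_blunt), cand, cb$reference)
  expect_equal(al$nuclear$end, 10000L)
  expect_equal(al$mt$start, 1999L)     # 0-based fragment start
  expect_equal(al$overlap_len, 0L)
  expect_equal(al$unaligned_gap, 0L)

  # all-N clipped bases yield no alignment
  aln <- realign_split_read(
    make_read("rn", "chr1", 9925, "75M75S",
              paste0(substr(A, 9926, 10000), strrep("N", 75))),
    cand, cb$reference)
  expect_null(aln)
})

test_that("modal breakpoints need three split reads; ties go low", {
  cb <- tiny_cohort()
  cand <- data.frame(sample_id = "S0001", nuclear_contig = "chr1",
                     nuclear_start = 9700L, nuclear_end = 10300L,
                     mt_start = 1999L, mt_end = 2499L, support = 10L,
                     orientation = "x", candidate_id = "cand1")
  mk_aln <- function(nuc_end, mt_start) {
    list(read_id = "r", sample_id = "S0001",
         nuclear = list(contig = "chr1", start = nuc_end - 75L,
                        end = nuc_end, strand = "+",
                        query_start = 1L, query_end = 75L),
         mt = list(contig = "MT", start = mt_start, end = mt_start + 75L,
                   strand = "+", query_start = 76L, query_end = 150L),
         overlap_len = 0L, unaligned_gap = 0L, inserted_seq = "",
         nuclear_first = TRUE)
  }
  # two reads only: no breakpoint for the side
  two <- define_breakpoints(list(mk_aln(10000L, 1999L), mk_aln(10000L, 1999L)),
                            cand)
  expect_null(two$breakpoints)
  # positions {1000,1000,1001}-style tie-break: modal then smallest
  three <- define_breakpoints(list(mk_aln(1000L, 1999L), mk_aln(1000L, 1999L),
                                   mk_aln(1001L, 1999L)), cand)
  nuc <- three$breakpoints[three$breakpoints$side == "nuclear", ]
  expect_equal(nuc$position, 1000L)
  expect_equal(nuc$split_support, 3L)
  even <- define_breakpoints(list(mk_aln(1000L, 1999L), mk_aln(1001L, 1999L),
                                  mk_aln(1001L, 1999L), mk_aln(1000L, 1999L)),
                             cand)
  expect_equal(even$breakpoints$position[
    even$breakpoints$side == "nuclear"], 1000L)
})

test_that("junction classes partition microhomology, blunt and insertion", {
  # string-oracle reference: nuclear ...ACGT | mt CCAG..., with "CCA"
  # present at both flank ends -> microhomology length 3
  left_flank <- paste0(strrep("T", 60), "ACGTCCA")
  mt_seq <- paste0("CCAGT", strrep("A", 20), strrep("C", 15),
                   strrep("G", 700), strrep("T", 300))
  ref <- string_reference(paste0(left_flank, strrep("G", 40)), mt_seq)
  cls <- classify_junction(ref, "chr1", nuclear_bp = 67L, mt_bp = 1L,
                           junction = "left")
  expect_equal(cls$class, "microhomology")
  expect_equal(cls$microhomology_len, 3L)

  # clean abutment: blunt
  ref2 <- string_reference(paste0(strrep("T", 60), "ACGT", strrep("T", 30)),
                           mt_seq)
  cls2 <- classify_junction(ref2, "chr1", nuclear_bp = 64L, mt_bp = 1L,
                            junction = "left")
  expect_equal(cls2$class, "blunt")
  expect_equal(cls2$microhomology_len, 0L)

  # junction bases matching neither side: insertion of length 2
  cls3 <- classify_junction(ref2, "chr1", nuclear_bp = 64L, mt_bp = 1L,
                            junction = "left", inserted_seq = "TT")
  expect_equal(cls3$class, "insertion")
  expect_equal(nchar(cls3$inserted_seq), 2L)

  expect_error(classify_junction(ref2, "chr1", NA, 1L, "left"),
               "defined")
})

test_that("pipeline junction classes and positions match planted truth", {
  cb <- tiny_cohort()
  expected <- list(
    S0001 = data.frame(class = c("blunt", "blunt", "insertion", "blunt"),
                       mt_bp = c(2000, 2499, 5399, 5000)),
    S0002 = data.frame(class = c("blunt", "blunt"), mt_bp = c(2000, 2499)),
    S0003 = data.frame(class = c("microhomology", "blunt"),
                       mt_bp = c(16400, 300))
  )
  for (s in names(expected)) {
    cands <- detect_numts(cb$reads[[s]], cb$reference, min_support = 2)
    bp <- refine_breakpoints(cb$reads[[s]], cands, cb$reference)
    jc <- bp$junction_classes[order(bp$junction_classes$numt_id,
                                    bp$junction_classes$junction), ]
    exp <- expected[[s]]
    expect_equal(nrow(jc), nrow(exp))
    expect_setequal(paste(jc$class, jc$mt_bp),
                    paste(exp$class, exp$mt_bp))
    # nuclear breakpoints are exact
    truth <- cb$planted$truth
    for (k in seq_len(nrow(jc))) {
      tr <- truth[truth$sample_id == s &
                    abs(truth$nuclear_pos - jc$nuclear_bp[k]) <= 10, ]
      expect_equal(jc$nuclear_bp[k], tr$nuclear_pos[1])
    }
  }
  # microhomology length matches the declared spec
  cands <- detect_numts(cb$reads$S0003, cb$reference, min_support = 2)
  bp <- refine_breakpoints(cb$reads$S0003, cands, cb$reference)
  mh <- bp$junction_classes[bp$junction_classes$class == "microhomology", ]
  expect_equal(mh$microhomology_len, 3L)
})

test_that("trinucleotide and poly-C context follow the stated null", {
  # mt genome engineered so breakpoints sit right after a CCCC run
  mt <- paste0(strrep("A", 500), "CCCC", strrep("G", 10), strrep("T", 486),
               strrep("ACGT", 100))
  ref <- string_reference(strrep("A", 2000), mt)
  # mt_left breakpoints at position 505 ("beyond" = 501..504 all C)
  bps <- data.frame(numt_id = sprintf("n%d", 1:6), side = "mt_left",
                    contig = NA, position = 505L, split_support = 3L,
                    mt_strand = "+", junction = "left")
  ctx <- breakpoint_sequence_context(bps, ref, ks = 2:4)
  f_c <- sum(strsplit(mt, "")[[1]] == "C") / nchar(mt)
  for (k in 2:4) {
    row <- ctx$polyc[ctx$polyc$k == k, ]
    expect_equal(row$observed, 6L)
    expect_equal(row$expected, 6 * f_c^k, tolerance = 1e-12)
    expect_equal(row$fold, 1 / f_c^k, tolerance = 1e-12)
    expect_lt(row$p_value, 0.01)
  }
  # trinucleotide tallies sum to the number of breakpoints scored
  expect_equal(sum(ctx$trinucleotide$count), nrow(bps))
  # centered context at 505 is CGG (bases 504..506)
  expect_equal(ctx$trinucleotide$trinucleotide[1], "CGG")

  # strand-reversed NUMT: context is reverse-complemented (manual oracle)
  bps_m <- transform(bps, mt_strand = "-")
  ctx_m <- breakpoint_sequence_context(bps_m, ref, ks = 2)
  expect_equal(ctx_m$trinucleotide$trinucleotide[1], revcomp("CGG"))
})
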