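# Shared fixture builders: tiny simulated cohorts assembled in code.

# A minimal three-sample cohort with one plus-strand, one origin-wrapping
# and one minus-strand NUMT; used by several module tests.
tiny_cohort <- local({
  cache <- list()
  function(seed = 42) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- tiny_cohort_build(seed)
    cache[[key]] <<- out
    out
  }
})

tiny_cohort_build <- function(seed = 42) {
  ref <- build_toy_references(c(chr1 = 50000, chr2 = 30000), seed = 11)
  des <- cohort_design(n_samples = 3, seed = seed)
  numts <- list(
    simulated_numt("n1", "chr1", 10000,
                   data.frame(mt_start = 2000, mt_end = 2499,
                              orientation = "+"),
                   carriers = c("S0001", "S0002")),
    simulated_numt("n2", "chr2", 8000,
                   data.frame(mt_start = 16400, mt_end = 300,
                              orientation = "+"),
                   carriers = "S0003", mh_len = 3),
    simulated_numt("n3", "chr1", 30000,
                   data.frame(mt_start = 5000, mt_end = 5399,
                              orientation = "-"),
                   carriers = "S0001", inserted_bases = "TTAG")
  )
  planted <- plant_numts(ref, numts, des)
  list(reference = planted$reference, design = des, numts = numts,
       planted = planted, reads = simulate_cohort_reads(planted))
}

# hand-built alignment record in the canonical column layout
make_read <- function(read_id, contig, start, cigar, seq,
                      mate_contig = contig, mate_start = start,
                      mapq = 60L, flag = 1L + 64L, sample_id = "S1",
                      strand = "+", is_first = TRUE) {
  data.frame(read_id = read_id, sample_id = sample_id, flag = flag,
             contig = contig, start = start, mapq = mapq, cigar = cigar,
             strand = strand, mate_contig = mate_contig,
             mate_start = mate_start, seq = seq, is_first = is_first,
             is_supplementary = FALSE)
}

# a discordant chr/MT pair as two records
make_pair <- function(id, nuc_contig, nuc_start, mt_start,
                      nuc_mapq = 60L, mt_mapq = 60L, sample_id = "S1",
                      nuc_strand = "+", mt_strand = "-", rl = 100L) {
  seq <- strrep("A", rl)
  rbind(
    make_read(id, nuc_contig, nuc_start, paste0(rl, "M"), seq,
              mate_contig = "MT", mate_start = mt_start, mapq = nuc_mapq,
              sample_id = sample_id, strand = nuc_strand, is_first = TRUE),
    make_read(id, "MT", mt_start, paste0(rl, "M"), seq,
              mate_contig = nuc_contig, mate_start = nuc_start,
              mapq = mt_mapq, sample_id = sample_id, strand = mt_strand,
              is_first = FALSE, flag = 1L + 128L)
  )
}

# plain reference with fixed sequences for oracle-style string tests
string_reference <- function(chr1, mt) {
  reference_genome(c(chr1 = chr1, MT = mt), mt_name = "MT")
}
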