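# Base-pair breakpoint refinement from soft-clipped split reads, junction
# mechanism classification (microhomology / blunt / insertion) and junction
# sequence context (trinucleotides, poly-C tracts beyond the mt breakpoint).

.nuc_sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -2,
                                                     baseOnly = FALSE)
    m
  }
})

# Best ungapped-ish local alignment of `query` against `subject`, both
# strands. Gaps are effectively forbidden (heavy penalties): split reads from
# substitution-only data realign without indels. Returns NULL or a list with
# subject_start/subject_end (0-based half-open), query_start/query_end
# (1-based inclusive, in original read orientation), strand, score, matches.
.best_local_direct <- function(query, subject, subject_offset = 0L) {
  if (nchar(query) < 1 || nchar(subject) < 1) return(NULL)
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    al <- Biostrings::pairwiseAlignment(
      q, subject, type = "local", substitutionMatrix = .nuc_sub_matrix(),
      gapOpening = 1000, gapExtension = 1000)
    sc <- Biostrings::score(al)
    if (is.null(best) || sc > best$score) {
      pr <- al@pattern@range
      sr <- al@subject@range
      qs <- IRanges::start(pr); qe <- IRanges::end(pr)
      n <- nchar(query)
      if (strand == "-") { tmp <- qs; qs <- n - qe + 1L; qe <- n - tmp + 1L }
      nmatch <- Biostrings::nmatch(al)
      best <- list(subject_start = subject_offset + IRanges::start(sr) - 1L,
                   subject_end = subject_offset + IRanges::end(sr),
                   query_start = qs, query_end = qe, strand = strand,
                   score = sc, matches = nmatch,
                   aligned_len = IRanges::width(pr),
                   identity = nmatch / IRanges::width(pr),
                   aligned_seq = as.character(al@subject))
    }
  }
  best
}

# Seeded local alignment for large subjects: exact 20-mer seeds from the
# query ends and middle (both strands) locate candidate windows, and the
# dynamic programming runs only inside them. Falls back to the full-subject
# alignment when no seed hits (e.g. error-dense reads).
.best_local <- function(query, subject, subject_offset = 0L,
                        seed_width = 20L, direct_below = 4000L) {
  n <- nchar(query)
  if (nchar(subject) <= direct_below || n < seed_width)
    return(.best_local_direct(query, subject, subject_offset))
  seeds <- character(0)
  for (q in c(query, revcomp(query))) {
    mid <- max(1L, (n - seed_width) %/% 2L)
    seeds <- c(seeds, substr(q, 1L, seed_width),
               substr(q, mid, mid + seed_width - 1L),
               substr(q, n - seed_width + 1L, n))
  }
  seeds <- unique(seeds[!grepl("N", seeds)])
  hits <- integer(0)
  for (s in seeds) {
    m <- Biostrings::matchPattern(s, subject)
    hits <- c(hits, IRanges::start(m))
  }
  if (length(hits) == 0)
    return(.best_local_direct(query, subject, subject_offset))
  lo <- pmax(1L, hits - n - 50L)
  hi <- pmin(nchar(subject), hits + n + 50L)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  keep_lo <- lo[1]; keep_hi <- hi[1]
  if (length(lo) > 1) for (i in seq(2, length(lo))) {
    k <- length(keep_lo)
    if (lo[i] <= keep_hi[k]) keep_hi[k] <- max(keep_hi[k], hi[i])
    else { keep_lo <- c(keep_lo, lo[i]); keep_hi <- c(keep_hi, hi[i]) }
  }
  best <- NULL
  for (i in seq_along(keep_lo)) {
    al <- .best_local_direct(query,
                             substr(subject, keep_lo[i], keep_hi[i]),
                             subject_offset + keep_lo[i] - 1L)
    if (!is.null(al) && (is.null(best) || al$score > best$score)) best <- al
  }
  best
}

#' Collect split (soft-clipped) reads near a candidate
#'
#' @param reads per-sample alignment data.frame.
#' @param candidate one row of [call_candidates()] output.
#' @param reference a `numt_reference`.
#' @param min_clip minimum soft-clip length (default 20 bp).
#' @param window distance from the candidate spans within which the aligned
#'   portion must fall (default 1,000 bp).
#' @return subset of `reads` carrying a qualifying soft clip.
#' @export
collect_split_reads <- function(reads, candidate, reference,
                                min_clip = 20L, window = 1000L) {
  r <- reads[!is.na(reads$contig) & reads$mapq > 0, , drop = FALSE]
  if (nrow(r) == 0) return(r)
  clips <- .clips_vec(r$cigar)
  has_clip <- pmax(clips[, 1], clips[, 2]) >= min_clip
  r <- r[has_clip, , drop = FALSE]
  if (nrow(r) == 0) return(r)
  ref_len <- vapply(r$cigar, cigar_reference_length, 0L)
  near_nuc <- r$contig == candidate$nuclear_contig &
    r$start <= candidate$nuclear_end + window &
    (r$start + ref_len) >= candidate$nuclear_start - window
  mt_len <- reference$mt_length
  span <- c(candidate$mt_start, candidate$mt_end)
  near_mt <- r$contig == reference$mt_name &
    vapply(seq_len(nrow(r)), function(i) {
      .circular_span_gap(span[1], span[2], r$start[i],
                         r$start[i] + ref_len[i], mt_len) <= window
    }, logical(1))
  r[near_nuc | near_mt, , drop = FALSE]
}

#' Realign a soft-clipped read across a putative nuclear-mt junction
#'
#' The full read is locally aligned (match +1, mismatch -2, gaps forbidden;
#' both strands) against the candidate's nuclear window (+/- 1,000 bp) and
#' against the full mtDNA. Accepted when the mt segment aligns >= `min_len`
#' bases at >= `min_identity`. Microhomology appears as overlap of the two
#' segments' query intervals; non-templated junction bases as a query gap
#' covered by neither.
#'
#' @param read one alignment row (its `seq` is used).
#' @param candidate candidate row (defines the nuclear window).
#' @param reference a `numt_reference`.
#' @param min_len minimum aligned length per segment.
#' @param min_identity minimum identity per segment.
#' @param window nuclear window half-width.
#' @return NULL, or a list: `nuclear` and `mt` segment lists (contig,
#'   start/end 0-based half-open, strand, query_start/query_end),
#'   `overlap_len`, `unaligned_gap`, `inserted_seq`, `nuclear_first`
#'   (whether the nuclear segment covers the query prefix).
#' @export
realign_split_read <- function(read, candidate, reference, min_len = 20L,
                               min_identity = 0.9, window = 1000L) {
  q <- read$seq
  if (gsub("N", "", q) == "") return(NULL)
  ctg <- candidate$nuclear_contig
  nuc_seq <- reference$contigs[[ctg]]
  w_start <- max(0L, candidate$nuclear_start - window)
  w_end <- min(nchar(nuc_seq), candidate$nuclear_end + window)
  nuc_al <- .best_local(q, substr(nuc_seq, w_start + 1L, w_end),
                        subject_offset = w_start)
  mt_al <- .best_local(q, reference$contigs[[reference$mt_name]])
  if (is.null(nuc_al) || is.null(mt_al)) return(NULL)
  if (mt_al$aligned_len < min_len || mt_al$identity < min_identity)
    return(NULL)
  if (nuc_al$aligned_len < min_len || nuc_al$identity < min_identity)
    return(NULL)
  # ambiguity: a perfect mt segment with multiple exact placements
  if (mt_al$identity == 1) {
    hits <- Biostrings::countPattern(
      mt_al$aligned_seq, reference$contigs[[reference$mt_name]])
    hits <- hits + Biostrings::countPattern(
      revcomp(mt_al$aligned_seq), reference$contigs[[reference$mt_name]])
    if (hits > 1) return(NULL)
  }
  nuclear_first <- nuc_al$query_start <= mt_al$query_start
  left <- if (nuclear_first) nuc_al else mt_al
  right <- if (nuclear_first) mt_al else nuc_al
  overlap <- max(0L, left$query_end - right$query_start + 1L)
  gap <- max(0L, right$query_start - left$query_end - 1L)
  inserted <- if (gap > 0)
    substr(q, left$query_end + 1L, right$query_start - 1L) else ""
  seg <- function(al, contig) list(contig = contig, start = al$subject_start,
                                   end = al$subject_end, strand = al$strand,
                                   query_start = al$query_start,
                                   query_end = al$query_end)
  list(read_id = read$read_id, sample_id = read$sample_id,
       nuclear = seg(nuc_al, ctg), mt = seg(mt_al, reference$mt_name),
       overlap_len = overlap, unaligned_gap = gap, inserted_seq = inserted,
       nuclear_first = nuclear_first)
}

# Flatten split alignments into per-read junction observations.
.junction_observations <- function(split_alns) {
  if (length(split_alns) == 0)
    return(data.frame(junction = character(0), nuclear_bp = integer(0),
                      mt_bp = integer(0), mt_strand = character(0),
                      overlap_len = integer(0), gap = integer(0),
                      inserted_seq = character(0),
                      sample_id = character(0)))
  do.call(rbind, lapply(split_alns, function(a) {
    # physical junction side: reads are stored reference-forward w.r.t.
    # their primary contig, so the query order flips when the nuclear
    # segment aligns to the minus strand
    phys_left <- a$nuclear_first == (a$nuclear$strand == "+")
    # junction-adjacent mt boundary (keyed on query order)
    mt_bp <- if (a$nuclear_first) {
      if (a$mt$strand == "+") a$mt$start + 1L else a$mt$end
    } else {
      if (a$mt$strand == "+") a$mt$end else a$mt$start + 1L
    }
    # insert orientation on mtDNA relative to the nuclear forward strand
    ori <- if (a$nuclear$strand == a$mt$strand) "+" else "-"
    nuclear_bp <- if (phys_left) a$nuclear$end else a$nuclear$start
    ins <- a$inserted_seq
    if (nzchar(ins) && a$nuclear$strand == "-") ins <- revcomp(ins)
    data.frame(junction = if (phys_left) "left" else "right",
               nuclear_bp = nuclear_bp, mt_bp = mt_bp,
               mt_strand = ori, overlap_len = a$overlap_len,
               gap = a$unaligned_gap, inserted_seq = ins,
               sample_id = a$sample_id)
  }))
}

# modal value; ties broken to the smallest (numeric or lexicographic)
.modal <- function(x) {
  x <- as.integer(x)
  tab <- table(x)
  min(as.integer(names(tab)[tab == max(tab)]))
}
.modal_chr <- function(x) {
  x <- as.character(x)
  tab <- table(x, useNA = "no")
  if (length(tab) == 0) return(NA_character_)
  min(names(tab)[tab == max(tab)])
}

#' Define breakpoints from split-read alignments
#'
#' Per junction side, the modal position among supporting split reads is
#' reported (ties to the smaller coordinate); a side needs at least
#' `min_split` split reads. A candidate with more than one well-supported
#' nuclear breakpoint is flagged complex.
#'
#' @param split_alns list of [realign_split_read()] results.
#' @param candidate candidate row (provides the id).
#' @param min_split minimum split reads per breakpoint (default 3).
#' @return list with `breakpoints` (data.frame: `numt_id`, `side` in
#'   nuclear/mt_left/mt_right, `contig`, `position` 1-based,
#'   `split_support`, `mt_strand`, `junction`), `junctions` (per-side modal
#'   overlap/gap/inserted bases) and `complex` flag.
#' @export
define_breakpoints <- function(split_alns, candidate, min_split = 3L) {
  obs <- .junction_observations(split_alns)
  bps <- NULL
  juncs <- NULL
  complex_flag <- FALSE
  nuclear_positions <- integer(0)
  for (side in c("left", "right")) {
    o <- obs[obs$junction == side, , drop = FALSE]
    if (nrow(o) < min_split) next
    nuc_bp <- .modal(o$nuclear_bp)
    mt_bp <- .modal(o$mt_bp)
    strand <- .modal_chr(o$mt_strand)
    support <- nrow(o)
    nuclear_positions <- c(nuclear_positions, nuc_bp)
    # check for a secondary well-supported nuclear position
    tab <- table(o$nuclear_bp)
    if (sum(tab >= min_split & abs(as.integer(names(tab)) - nuc_bp) > 5) > 0)
      complex_flag <- TRUE
    mt_side <- if ((side == "left") == (strand == "+")) "mt_left" else "mt_right"
    bps <- rbind(bps,
      data.frame(numt_id = candidate$candidate_id, side = "nuclear",
                 contig = candidate$nuclear_contig, position = nuc_bp,
                 split_support = support, mt_strand = strand,
                 junction = side),
      data.frame(numt_id = candidate$candidate_id, side = mt_side,
                 contig = NA_character_, position = mt_bp,
                 split_support = support, mt_strand = strand,
                 junction = side))
    juncs <- rbind(juncs, data.frame(
      numt_id = candidate$candidate_id, junction = side,
      overlap_len = .modal(o$overlap_len), gap = .modal(o$gap),
      inserted_seq = .modal_chr(o$inserted_seq), mt_strand = strand,
      nuclear_bp = nuc_bp, mt_bp = mt_bp))
  }
  if (length(unique(nuclear_positions)) > 1 &&
      diff(range(nuclear_positions)) > 5)
    complex_flag <- TRUE
  list(breakpoints = bps, junctions = juncs, complex = complex_flag)
}

#' Classify the repair mechanism of a junction
#'
#' Microhomology is the longest identical overlap (up to `max_scan` bp)
#' between the nuclear flank and the mt flank across the junction; junction
#' bases aligning to neither reference make the insertion class; otherwise
#' the junction is blunt. Exactly one class is assigned.
#'
#' @param reference a `numt_reference`.
#' @param nuclear_contig,nuclear_bp nuclear side: contig and 1-based position
#'   of the last nuclear base before the insert.
#' @param mt_bp 1-based mt position of the fragment boundary at this
#'   junction.
#' @param junction `"left"` (nuclear then mt in reference-forward order) or
#'   `"right"`.
#' @param mt_strand insert orientation on mtDNA.
#' @param inserted_seq non-templated junction bases observed in split reads
#'   (empty if none).
#' @param max_scan homology scan cap (default 30 bp).
#' @return data.frame: `class`, `microhomology_len`, `inserted_seq`.
#' @export
classify_junction <- function(reference, nuclear_contig, nuclear_bp, mt_bp,
                              junction = c("left", "right"),
                              mt_strand = "+", inserted_seq = "",
                              max_scan = 30L) {
  junction <- match.arg(junction)
  if (is.na(nuclear_bp) || is.na(mt_bp))
    stop("breakpoints must be defined on both sides of the junction")
  nuc <- reference$contigs[[nuclear_contig]]
  mt <- reference$contigs[[reference$mt_name]]
  L <- reference$mt_length
  circ_sub <- function(from, len) {
    idx <- (((from - 1L) + seq_len(len) - 1L) %% L) + 1L
    paste(vapply(idx, function(i) substr(mt, i, i), character(1)),
          collapse = "")
  }
  if (junction == "left") {
    nuc_tail <- substr(nuc, max(1L, nuclear_bp - max_scan + 1L), nuclear_bp)
    mt_head <- if (mt_strand == "+") circ_sub(mt_bp, max_scan)
               else revcomp(circ_sub(((mt_bp - max_scan) %% L) + 1L,
                                     max_scan))
    mh <- .overlap_scan(nuc_tail, mt_head, cap = max_scan)
  } else {
    mt_tail <- if (mt_strand == "+")
      circ_sub(((mt_bp - max_scan) %% L) + 1L, max_scan)
    else revcomp(circ_sub(mt_bp, max_scan))
    nuc_head <- substr(nuc, nuclear_bp + 1L,
                       min(nchar(nuc), nuclear_bp + max_scan))
    mh <- .overlap_scan(mt_tail, nuc_head, cap = max_scan)
  }
  if (nzchar(inserted_seq) && !is.na(inserted_seq)) {
    cls <- "insertion"; mh_out <- 0L; ins <- inserted_seq
  } else if (mh >= 1) {
    cls <- "microhomology"; mh_out <- mh; ins <- ""
  } else {
    cls <- "blunt"; mh_out <- 0L; ins <- ""
  }
  data.frame(class = cls, microhomology_len = mh_out, inserted_seq = ins)
}

#' Sequence context of breakpoints
#'
#' Tallies the trinucleotide centered on each breakpoint base (+/- 1 bp) into
#' 64 classes, separately for the nuclear and mt sides (reverse-oriented
#' inserts are reverse-complemented first), and measures poly-C extension:
#' for each k the number of mt breakpoints whose k bases immediately beyond
#' the fragment boundary are all C (all G for minus-strand inserts), against
#' the i.i.d. mononucleotide expectation N x f^k with a binomial test.
#'
#' @param breakpoints data.frame from [define_breakpoints()] (rows from
#'   several candidates may be concatenated).
#' @param reference a `numt_reference`.
#' @param ks poly-C extension lengths (default 2:4).
#' @return list: `trinucleotide` (data.frame side, trinucleotide, count) and
#'   `polyc` (data.frame k, observed, expected, fold, p_value, n_scored).
#' @export
breakpoint_sequence_context <- function(breakpoints, reference, ks = 2:4) {
  mt <- reference$contigs[[reference$mt_name]]
  L <- reference$mt_length
  circ_sub <- function(from, len) {
    idx <- (((from - 1L) + seq_len(len) - 1L) %% L) + 1L
    paste(vapply(idx, function(i) substr(mt, i, i), character(1)),
          collapse = "")
  }
  tri <- NULL
  skipped <- 0L
  for (i in seq_len(nrow(breakpoints))) {
    b <- breakpoints[i, ]
    if (b$side == "nuclear") {
      seqc <- reference$contigs[[b$contig]]
      if (b$position < 2 || b$position > nchar(seqc) - 1) {
        skipped <- skipped + 1L; next
      }
      t3 <- substr(seqc, b$position - 1L, b$position + 1L)
      side <- "nuclear"
    } else {
      t3 <- circ_sub(((b$position - 2L) %% L) + 1L, 3L)
      if (!is.na(b$mt_strand) && b$mt_strand == "-") t3 <- revcomp(t3)
      side <- "mt"
    }
    tri <- rbind(tri, data.frame(side = side, trinucleotide = t3))
  }
  tri_tab <- if (is.null(tri)) {
    data.frame(side = character(0), trinucleotide = character(0),
               count = integer(0))
  } else {
    agg <- as.data.frame(table(tri$side, tri$trinucleotide),
                         stringsAsFactors = FALSE)
    names(agg) <- c("side", "trinucleotide", "count")
    agg[agg$count > 0, , drop = FALSE]
  }
  # poly-C beyond the mt breakpoint
  mtb <- breakpoints[breakpoints$side %in% c("mt_left", "mt_right"), ,
                     drop = FALSE]
  comp <- table(strsplit(mt, "")[[1]])
  f_c <- unname(comp["C"] / L)
  f_g <- unname(comp["G"] / L)
  polyc <- do.call(rbind, lapply(ks, function(k) {
    obs <- 0L; exp_p <- numeric(0)
    for (i in seq_len(nrow(mtb))) {
      b <- mtb[i, ]
      outward <- if (b$side == "mt_left")
        circ_sub(((b$position - k - 1L) %% L) + 1L, k)
      else circ_sub(b$position %% L + 1L, k)
      minus <- !is.na(b$mt_strand) && b$mt_strand == "-"
      target <- if (minus) "G" else "C"
      if (outward == strrep(target, k)) obs <- obs + 1L
      exp_p <- c(exp_p, if (minus) f_g^k else f_c^k)
    }
    expected <- sum(exp_p)
    p <- if (nrow(mtb) > 0)
      binom.test(obs, nrow(mtb), p = mean(exp_p))$p.value else NA_real_
    data.frame(k = k, observed = obs, expected = expected,
               fold = if (expected > 0) obs / expected else NA_real_,
               p_value = p, n_scored = nrow(mtb))
  }))
  list(trinucleotide = tri_tab, polyc = polyc, skipped = skipped)
}

#' Breakpoint refinement for a set of candidates
#'
#' Runs split-read collection, realignment, breakpoint definition and
#' junction classification for each candidate of one sample.
#'
#' @param reads per-sample alignment data.frame.
#' @param candidates data.frame from [call_candidates()].
#' @param reference a `numt_reference`.
#' @param min_clip,min_split thresholds (see the individual operations).
#' @param max_reads cap on realigned split reads per candidate (the
#'   earliest by position are kept; breakpoints need only a modest pile-up).
#' @return list with `breakpoints`, `junction_classes` (one row per defined
#'   junction with class), `complex` (named logical per candidate) and
#'   `n_ambiguous` realignments.
#' @export
refine_breakpoints <- function(reads, candidates, reference,
                               min_clip = 20L, min_split = 3L,
                               max_reads = 40L) {
  all_bp <- NULL; all_cls <- NULL
  complexes <- logical(0); n_ambig <- 0L
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    sr <- collect_split_reads(reads, cand, reference, min_clip = min_clip)
    if (nrow(sr) > max_reads) {
      sr <- sr[order(sr$contig, sr$start), , drop = FALSE]
      sr <- sr[unique(round(seq(1, nrow(sr), length.out = max_reads))), ,
               drop = FALSE]
    }
    alns <- list()
    for (j in seq_len(nrow(sr))) {
      a <- realign_split_read(sr[j, ], cand, reference)
      if (is.null(a)) n_ambig <- n_ambig + 1L else alns[[length(alns) + 1]] <- a
    }
    db <- define_breakpoints(alns, cand, min_split = min_split)
    complexes[cand$candidate_id] <- db$complex
    if (!is.null(db$breakpoints)) all_bp <- rbind(all_bp, db$breakpoints)
    if (!is.null(db$junctions)) {
      for (j in seq_len(nrow(db$junctions))) {
        jn <- db$junctions[j, ]
        cls <- classify_junction(reference, cand$nuclear_contig,
                                 jn$nuclear_bp, jn$mt_bp,
                                 junction = jn$junction,
                                 mt_strand = jn$mt_strand,
                                 inserted_seq = jn$inserted_seq)
        all_cls <- rbind(all_cls, cbind(
          data.frame(numt_id = jn$numt_id, junction = jn$junction,
                     nuclear_bp = jn$nuclear_bp, mt_bp = jn$mt_bp,
                     mt_strand = jn$mt_strand), cls))
      }
    }
  }
  list(breakpoints = all_bp, junction_classes = all_cls,
       complex = complexes, n_ambiguous = n_ambig)
}
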