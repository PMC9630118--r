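# Candidate NUMT calling from nuclear-mt discordant read pairs.
#
# A discordant pair has one mate anchored on a nuclear contig and the other
# on the mitochondrial contig; pairs where either end has MAPQ 0 are
# discarded. Anchors sharing a (nuclear contig, orientation signature) are
# single-linkage clustered at 500 bp, clusters below the support threshold
# are dropped, and surviving clusters within 1,000 bp on both genomes
# (circular distance on mtDNA) are merged into one candidate.

#' Extract nuclear-mt discordant read pairs
#'
#' @param reads alignment data.frame for one sample
#'   (see [read_alignments()]).
#' @param reference a `numt_reference`.
#' @return data.frame of pairs: `sample_id`, `read_id`, `nuclear_contig`,
#'   `nuclear_start`, `nuclear_end` (0-based half-open anchor footprint),
#'   `nuclear_strand`, `mt_start`, `mt_end`, `mt_strand`.
#' @export
extract_discordant_pairs <- function(reads, reference) {
  mt <- reference$mt_name
  r <- reads[!reads$is_supplementary & !is.na(reads$contig), , drop = FALSE]
  if (nrow(r) == 0) return(.empty_pairs())
  # drop duplicated (read_id, mate) records, keep first occurrence
  r <- r[!duplicated(paste(r$read_id, r$is_first)), , drop = FALSE]
  counts <- table(r$read_id)
  both <- names(counts)[counts == 2]
  r <- r[r$read_id %in% both, , drop = FALSE]
  if (nrow(r) == 0) return(.empty_pairs())
  r <- r[order(r$read_id, !r$is_first), , drop = FALSE]
  first <- r[r$is_first, , drop = FALSE]
  last <- r[!r$is_first, , drop = FALSE]
  stopifnot(identical(first$read_id, last$read_id))
  f_mt <- first$contig == mt
  l_mt <- last$contig == mt
  keep <- (f_mt != l_mt) & first$mapq > 0 & last$mapq > 0
  first <- first[keep, , drop = FALSE]
  last <- last[keep, , drop = FALSE]
  if (nrow(first) == 0) return(.empty_pairs())
  pick <- first$contig == mt
  nuc_rec <- first; nuc_rec[pick, ] <- last[pick, ]
  mt_rec <- last; mt_rec[pick, ] <- first[pick, ]
  span <- function(rec) rec$start +
    vapply(rec$cigar, cigar_reference_length, 0L)
  data.frame(sample_id = nuc_rec$sample_id, read_id = nuc_rec$read_id,
             nuclear_contig = nuc_rec$contig, nuclear_start = nuc_rec$start,
             nuclear_end = span(nuc_rec), nuclear_strand = nuc_rec$strand,
             mt_start = mt_rec$start, mt_end = span(mt_rec),
             mt_strand = mt_rec$strand, row.names = NULL)
}

.empty_pairs <- function() {
  data.frame(sample_id = character(0), read_id = character(0),
             nuclear_contig = character(0), nuclear_start = integer(0),
             nuclear_end = integer(0), nuclear_strand = character(0),
             mt_start = integer(0), mt_end = integer(0),
             mt_strand = character(0))
}

#' Cluster discordant pairs
#'
#' Single-linkage clustering of nuclear anchor start positions at the given
#' distance, separately per (nuclear contig, orientation signature) where the
#' orientation signature is the (nuclear strand, mt strand) pair of the two
#' anchors. In one dimension single linkage reduces to splitting the sorted
#' anchor starts at gaps exceeding the distance.
#'
#' @param pairs data.frame from [extract_discordant_pairs()].
#' @param max_gap linkage distance in bp (default 500).
#' @return the input with a `cluster_id` column.
#' @export
cluster_pairs <- function(pairs, max_gap = 500L) {
  if (nrow(pairs) == 0) {
    pairs$cluster_id <- character(0)
    return(pairs)
  }
  sig <- paste(pairs$nuclear_contig, pairs$nuclear_strand, pairs$mt_strand,
               sep = "/")
  pairs$cluster_id <- NA_character_
  for (s in unique(sig)) {
    idx <- which(sig == s)
    o <- idx[order(pairs$nuclear_start[idx])]
    starts <- pairs$nuclear_start[o]
    newc <- c(TRUE, diff(starts) > max_gap)
    pairs$cluster_id[o] <- paste0(s, "#", cumsum(newc))
  }
  pairs
}

#' Call candidate NUMTs from clusters
#'
#' Clusters below `min_support` discordant pairs are removed; surviving
#' clusters whose nuclear spans are within `merge_dist` on the nuclear genome
#' AND whose mt spans are within `merge_dist` (circular distance) are merged
#' into a single candidate with summed support.
#'
#' @param clustered data.frame from [cluster_pairs()].
#' @param reference a `numt_reference`.
#' @param min_support minimum discordant pairs per cluster (2 for the
#'   sensitive set, 5 for the stringent set).
#' @param merge_dist grouping distance in bp (default 1,000).
#' @param max_span maximum nuclear cluster footprint; clusters wider than
#'   this are dropped as unphysical (default 2 x the insert mean ~ 800 bp,
#'   passed by callers that know the library).
#' @return data.frame of candidates: `sample_id`, `nuclear_contig`,
#'   `nuclear_start`, `nuclear_end`, `mt_start`, `mt_end` (0-based half-open;
#'   mt span may wrap, in which case `mt_end < mt_start`), `support`,
#'   `orientation`.
#' @export
call_candidates <- function(clustered, reference, min_support = 5L,
                            merge_dist = 1000L, max_span = Inf) {
  if (min_support < 1) stop("configuration error: min_support < 1")
  if (nrow(clustered) == 0) return(.empty_candidates())
  mt_len <- reference$mt_length
  cl <- split(clustered, clustered$cluster_id)
  cand <- do.call(rbind, lapply(cl, function(x) {
    mt_span <- .circular_span(x$mt_start, x$mt_end, mt_len)
    data.frame(sample_id = x$sample_id[1],
               nuclear_contig = x$nuclear_contig[1],
               nuclear_start = min(x$nuclear_start),
               nuclear_end = max(x$nuclear_end),
               mt_start = mt_span[1], mt_end = mt_span[2],
               support = nrow(x),
               orientation = paste(x$nuclear_strand[1], x$mt_strand[1],
                                   sep = "/"))
  }))
  cand <- cand[cand$support >= min_support &
                 (cand$nuclear_end - cand$nuclear_start) <= max_span, ,
               drop = FALSE]
  if (nrow(cand) == 0) return(.empty_candidates())
  # merge candidates within merge_dist on both genomes (single linkage)
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (cand$nuclear_contig[i] != cand$nuclear_contig[j]) next
    nuc_gap <- max(cand$nuclear_start[i], cand$nuclear_start[j]) -
      min(cand$nuclear_end[i], cand$nuclear_end[j])
    if (nuc_gap > merge_dist) next
    mt_gap <- .circular_span_gap(cand$mt_start[i], cand$mt_end[i],
                                 cand$mt_start[j], cand$mt_end[j], mt_len)
    if (mt_gap > merge_dist) next
    parent[find(i)] <- find(j)
  }
  root <- vapply(seq_len(n), find, 0L)
  merged <- do.call(rbind, lapply(split(cand, root), function(x) {
    mt_pts <- c(x$mt_start, x$mt_end)
    sp <- if (nrow(x) == 1) c(x$mt_start, x$mt_end)
          else .circular_span(x$mt_start, x$mt_end, mt_len)
    data.frame(sample_id = x$sample_id[1],
               nuclear_contig = x$nuclear_contig[1],
               nuclear_start = min(x$nuclear_start),
               nuclear_end = max(x$nuclear_end),
               mt_start = sp[1], mt_end = sp[2],
               support = sum(x$support),
               orientation = paste(sort(unique(x$orientation)),
                                   collapse = ","))
  }))
  merged <- merged[order(merged$nuclear_contig, merged$nuclear_start), ,
                   drop = FALSE]
  merged$candidate_id <- sprintf("%s:%s:%d", merged$sample_id,
                                 merged$nuclear_contig, merged$nuclear_start)
  rownames(merged) <- NULL
  merged
}

.empty_candidates <- function() {
  data.frame(sample_id = character(0), nuclear_contig = character(0),
             nuclear_start = integer(0), nuclear_end = integer(0),
             mt_start = integer(0), mt_end = integer(0),
             support = integer(0), orientation = character(0),
             candidate_id = character(0))
}

# Minimal circular arc covering a set of [start, end) mt intervals.
# Returns c(start, end) 0-based half-open; end < start encodes wrapping.
.circular_span <- function(starts, ends, mt_len) {
  pts <- sort(unique(c(starts %% mt_len, ends %% mt_len)))
  if (length(pts) == 1) return(c(pts, pts))
  gaps <- diff(c(pts, pts[1] + mt_len))
  cut <- which.max(gaps)
  if (cut == length(pts)) c(pts[1], pts[length(pts)])
  else c(pts[cut + 1], pts[cut])
}

# Gap between two circular spans (0 if they overlap).
.circular_span_gap <- function(s1, e1, s2, e2, mt_len) {
  unroll <- function(s, e) if (e >= s) c(s, e) else c(s, e + mt_len)
  a <- unroll(s1, e1); b <- unroll(s2, e2)
  shifts <- c(-mt_len, 0, mt_len)
  min(vapply(shifts, function(sh) {
    lo <- max(a[1], b[1] + sh); hi <- min(a[2], b[2] + sh)
    max(0, lo - hi)
  }, 0))
}

#' Per-sample NUMT detection pipeline
#'
#' Convenience wrapper: discordant-pair extraction, clustering, candidate
#' calling.
#'
#' @param reads per-sample alignment data.frame.
#' @param reference a `numt_reference`.
#' @param min_support support threshold (see [call_candidates()]).
#' @param cluster_gap,merge_dist clustering/merging distances.
#' @return candidate data.frame (see [call_candidates()]).
#' @export
detect_numts <- function(reads, reference, min_support = 5L,
                         cluster_gap = 500L, merge_dist = 1000L) {
  pairs <- extract_discordant_pairs(reads, reference)
  clustered <- cluster_pairs(pairs, max_gap = cluster_gap)
  call_candidates(clustered, reference, min_support = min_support,
                  merge_dist = merge_dist)
}
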