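# Cohort-level unification of per-sample NUMT calls, population frequency
# classes (common / rare / ultra-rare / private), known-NUMT matching and
# cohort summary statistics.

#' Unify per-sample candidates into cohort NUMT loci
#'
#' Cross-sample single-linkage grouping with the same rule used within
#' samples: two calls belong to the same NUMT when their nuclear spans are
#' within `merge_dist` AND their mt spans are within `merge_dist` (circular
#' distance). The representative locus is the median of member coordinates
#' (refined breakpoints, when supplied, take precedence over cluster
#' footprints); ties round to the smaller coordinate.
#'
#' @param candidates row-bound [call_candidates()] output across samples.
#' @param reference a `numt_reference`.
#' @param merge_dist grouping distance (default 1,000 bp).
#' @param breakpoints optional refined breakpoint table
#'   (from [refine_breakpoints()], rows with `side == "nuclear"`), keyed by
#'   `numt_id` = candidate id.
#' @return data.frame: `cohort_numt_id`, `nuclear_contig`, `nuclear_start`,
#'   `nuclear_end`, `mt_start`, `mt_end`, `size_bp` (circular-aware),
#'   `carriers` (semicolon-joined sample ids), `n_carriers`, `total_support`,
#'   `member_ids` (candidate ids).
#' @export
unify_cohort_numts <- function(candidates, reference, merge_dist = 1000L,
                               breakpoints = NULL) {
  n <- nrow(candidates)
  if (n == 0)
    return(data.frame(cohort_numt_id = character(0),
                      nuclear_contig = character(0),
                      nuclear_start = integer(0), nuclear_end = integer(0),
                      mt_start = integer(0), mt_end = integer(0),
                      size_bp = integer(0), carriers = character(0),
                      n_carriers = integer(0), total_support = integer(0),
                      member_ids = character(0)))
  mt_len <- reference$mt_length
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ord <- order(candidates$nuclear_contig, candidates$nuclear_start)
  cd <- candidates[ord, , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (cd$nuclear_contig[j] != cd$nuclear_contig[i]) break
      nuc_gap <- cd$nuclear_start[j] - cd$nuclear_end[i]
      if (nuc_gap > merge_dist) break
      mt_gap <- .circular_span_gap(cd$mt_start[i], cd$mt_end[i],
                                   cd$mt_start[j], cd$mt_end[j], mt_len)
      if (mt_gap <= merge_dist) parent[find(i)] <- find(j)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  med_lo <- function(x) {        # median, ties to the smaller coordinate
    x <- sort(x)
    x[ceiling(length(x) / 2)]
  }
  groups <- split(seq_len(n), root)
  out <- do.call(rbind, lapply(groups, function(ix) {
    x <- cd[ix, , drop = FALSE]
    ns <- med_lo(x$nuclear_start); ne <- med_lo(x$nuclear_end)
    if (!is.null(breakpoints)) {
      bp <- breakpoints[breakpoints$side == "nuclear" &
                          breakpoints$numt_id %in% x$candidate_id, ,
                        drop = FALSE]
      if (nrow(bp) > 0) {
        ns <- med_lo(bp$position); ne <- ns
      }
    }
    sp <- if (nrow(x) == 1) c(x$mt_start, x$mt_end)
          else .circular_span(x$mt_start, x$mt_end, mt_len)
    size <- if (sp[2] >= sp[1]) sp[2] - sp[1] else mt_len - sp[1] + sp[2]
    carr <- sort(unique(x$sample_id))
    data.frame(nuclear_contig = x$nuclear_contig[1],
               nuclear_start = ns, nuclear_end = ne,
               mt_start = sp[1], mt_end = sp[2], size_bp = size,
               carriers = paste(carr, collapse = ";"),
               n_carriers = length(carr),
               total_support = sum(x$support),
               member_ids = paste(x$candidate_id, collapse = ";"))
  }))
  out <- out[order(out$nuclear_contig, out$nuclear_start), , drop = FALSE]
  out$cohort_numt_id <- sprintf("cn%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Assign frequency classes and known-NUMT status
#'
#' Carrier frequency F is computed over individuals (one genome each);
#' classes follow the thresholds common (F >= 1%), rare (0.1% <= F < 1%),
#' ultra-rare (F < 0.1%), with boundaries inclusive on the common and rare
#' side. A NUMT is private when its carriers are confined to one family, and
#' known when any known-NUMT interval overlaps the call extended by 500 bp
#' flanks on each side, regardless of the mtDNA fragment involved.
#'
#' @param cohort data.frame from [unify_cohort_numts()].
#' @param n_samples number of individuals in the cohort.
#' @param known optional `interval_track` of known NUMTs (nuclear, BED).
#' @param manifest optional manifest (`sample`, `family`) for privateness.
#' @param flank known-NUMT matching flank (default 500 bp each side).
#' @return input with `F`, `freq_class`, `private`, `known` columns.
#' @export
classify_frequency_and_known <- function(cohort, n_samples, known = NULL,
                                         manifest = NULL, flank = 500L) {
  if (nrow(cohort) == 0) {
    cohort$F <- numeric(0); cohort$freq_class <- character(0)
    cohort$private <- logical(0); cohort$known <- logical(0)
    return(cohort)
  }
  cohort$F <- cohort$n_carriers / n_samples
  cohort$freq_class <- ifelse(cohort$F >= 0.01, "common",
                              ifelse(cohort$F >= 0.001, "rare", "ultra_rare"))
  cohort$private <- NA
  if (!is.null(manifest)) {
    cohort$private <- vapply(cohort$carriers, function(cc) {
      carr <- strsplit(cc, ";")[[1]]
      fam <- manifest$family[match(carr, manifest$sample)]
      if (anyNA(fam)) stop("family manifest missing a carrier")
      length(unique(fam)) == 1
    }, logical(1))
  }
  cohort$known <- FALSE
  if (!is.null(known)) {
    iv <- known$intervals
    for (i in seq_len(nrow(cohort))) {
      lo <- cohort$nuclear_start[i] - flank
      hi <- cohort$nuclear_end[i] + flank
      cohort$known[i] <- any(iv$contig == cohort$nuclear_contig[i] &
                               iv$start < hi & iv$end > lo)
    }
  }
  cohort
}

#' Cohort summary statistics
#'
#' Per-individual NUMT counts (mean and standard deviation over all cohort
#' samples, carriers or not), the Pearson correlation between NUMT size and
#' population frequency, and a two-group rank-sum comparison utility.
#'
#' @param cohort annotated cohort table
#'   (from [classify_frequency_and_known()]).
#' @param sample_ids all cohort samples.
#' @return list: `per_individual` (data.frame sample, n_numts), `mean_numts`,
#'   `sd_numts`, `size_frequency` (list r, p, n; NA when fewer than three
#'   loci).
#' @export
cohort_summaries <- function(cohort, sample_ids) {
  counts <- setNames(integer(length(sample_ids)), sample_ids)
  for (cc in cohort$carriers) {
    carr <- strsplit(cc, ";")[[1]]
    counts[carr] <- counts[carr] + 1L
  }
  per_ind <- data.frame(sample = names(counts), n_numts = as.integer(counts))
  sf <- if (nrow(cohort) >= 3 && sd(cohort$size_bp) > 0 && sd(cohort$F) > 0) {
    ct <- cor.test(cohort$size_bp, cohort$F, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = nrow(cohort))
  } else list(r = NA_real_, p = NA_real_, n = nrow(cohort))
  list(per_individual = per_ind, mean_numts = mean(per_ind$n_numts),
       sd_numts = sd(per_ind$n_numts), size_frequency = sf)
}

#' Two-group rank-sum comparison
#'
#' Wilcoxon rank-sum wrapper used for cohort group contrasts (for example
#' per-individual NUMT counts in males versus females).
#'
#' @param x,y numeric vectors.
#' @return list `statistic`, `p`, `n_x`, `n_y`.
#' @export
ranksum_compare <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_x = length(x), n_y = length(y))
}
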