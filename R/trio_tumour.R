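# De novo (trio) and tumour-specific NUMT calling, exact binomial insertion
# rates, and 2x2 carrier association tests.

# Does any call in `tab` match the locus of `cand` (nuclear spans within
# merge_dist on the same contig AND mt spans within merge_dist circularly)?
# Returns the maximum support among matching calls (0 if none).
.locus_support <- function(cand, tab, mt_len, merge_dist = 1000L) {
  if (is.null(tab) || nrow(tab) == 0) return(0L)
  hit <- tab$nuclear_contig == cand$nuclear_contig &
    (pmax(tab$nuclear_start, cand$nuclear_start) -
       pmin(tab$nuclear_end, cand$nuclear_end)) <= merge_dist
  hit[hit] <- vapply(which(hit), function(j) {
    .circular_span_gap(cand$mt_start, cand$mt_end,
                       tab$mt_start[j], tab$mt_end[j], mt_len) <= merge_dist
  }, logical(1))
  if (!any(hit)) 0L else max(tab$support[hit])
}

# Uniqueness check for a putative de novo junction: the longest soft-clipped
# read at the locus must not have a second near-perfect placement in the
# nuclear genome (>= 95% identity over >= 90% of its length) outside the
# call region.
.junction_unique <- function(reads, cand, reference, min_identity = 0.95,
                             min_cover = 0.9) {
  sr <- collect_split_reads(reads, cand, reference)
  if (nrow(sr) == 0) return(TRUE)
  q <- sr$seq[which.max(nchar(sr$seq))]
  n <- nchar(q)
  for (ctg in setdiff(names(reference$contigs), reference$mt_name)) {
    subject <- reference$contigs[[ctg]]
    al <- .best_local(q, subject)
    if (is.null(al)) next
    inside <- ctg == cand$nuclear_contig &&
      al$subject_start < cand$nuclear_end + 1000 &&
      al$subject_end > cand$nuclear_start - 1000
    if (inside) next
    if (al$identity >= min_identity && al$aligned_len >= min_cover * n)
      return(FALSE)
  }
  TRUE
}

#' Call de novo NUMTs in trios
#'
#' A NUMT is de novo when the offspring call has at least `child_support`
#' discordant pairs, neither parent shows `parent_support` or more discordant
#' pairs at the locus (a deliberate sensitivity re-check below the main
#' calling threshold), and the junction-spanning sequence has no second
#' near-perfect placement in the nuclear reference.
#'
#' @param candidates_by_sample named list of per-sample candidate tables
#'   called at a permissive threshold (`min_support = 1`) so parental
#'   evidence at any support is visible.
#' @param manifest manifest with `sample`, `role`, `family`
#'   (see [design_manifest()]).
#' @param reference a `numt_reference`.
#' @param reads_by_sample optional named list of per-sample reads enabling
#'   the junction uniqueness check (skipped when absent).
#' @param child_support offspring threshold (default 5).
#' @param parent_support parental veto threshold (default 2).
#' @param merge_dist locus matching distance (default 1,000 bp).
#' @return data.frame of de novo calls (child candidate rows plus `family`);
#'   attribute `n_incomplete` counts skipped incomplete trios.
#' @export
call_de_novo <- function(candidates_by_sample, manifest, reference,
                         reads_by_sample = NULL, child_support = 5L,
                         parent_support = 2L, merge_dist = 1000L) {
  mt_len <- reference$mt_length
  out <- NULL
  n_incomplete <- 0L
  for (fam in unique(manifest$family[manifest$role == "child"])) {
    trio <- manifest[manifest$family == fam, ]
    child <- trio$sample[trio$role == "child"]
    father <- trio$sample[trio$role == "father"]
    mother <- trio$sample[trio$role == "mother"]
    if (length(child) != 1 || length(father) != 1 || length(mother) != 1 ||
        !all(c(child, father, mother) %in% names(candidates_by_sample))) {
      n_incomplete <- n_incomplete + 1L
      warning("incomplete trio for family ", fam, "; skipped")
      next
    }
    cc <- candidates_by_sample[[child]]
    if (is.null(cc) || nrow(cc) == 0) next
    for (i in seq_len(nrow(cc))) {
      cand <- cc[i, ]
      if (cand$support < child_support) next
      fs <- .locus_support(cand, candidates_by_sample[[father]], mt_len,
                           merge_dist)
      ms <- .locus_support(cand, candidates_by_sample[[mother]], mt_len,
                           merge_dist)
      if (fs >= parent_support || ms >= parent_support) next
      if (!is.null(reads_by_sample) &&
          !.junction_unique(reads_by_sample[[child]], cand, reference)) next
      out <- rbind(out, cbind(cand, family = fam))
    }
  }
  if (is.null(out)) {
    out <- cbind(.empty_candidates(), data.frame(family = character(0)))
  }
  attr(out, "n_incomplete") <- n_incomplete
  out
}

#' Call tumour-specific and lost NUMTs in tumour-normal pairs
#'
#' Tumour-specific: at least `somatic_support` discordant pairs in the
#' tumour and none at the locus in the matched normal. Lost: at least
#' `somatic_support` pairs in the normal and at most one in the tumour.
#' Strict mode additionally requires tumour-specific calls to be absent
#' from every other (non-cancer) genome in the cohort.
#'
#' @param candidates_by_sample named list of per-sample candidate tables at
#'   a permissive threshold (`min_support = 1`).
#' @param pairs list of `c(tumour, normal)` sample-id pairs.
#' @param reference a `numt_reference`.
#' @param somatic_support main threshold (default 5).
#' @param strict require cohort-wide absence for tumour-specific calls.
#' @param background_samples sample ids counted as the non-cancer cohort in
#'   strict mode (default: all samples not in any pair).
#' @param merge_dist locus matching distance.
#' @return list with `tumour_specific` and `lost` candidate data.frames
#'   (each with a `pair` column).
#' @export
call_tumour_specific <- function(candidates_by_sample, pairs, reference,
                                 somatic_support = 5L, strict = FALSE,
                                 background_samples = NULL,
                                 merge_dist = 1000L) {
  mt_len <- reference$mt_length
  paired_ids <- unlist(pairs)
  if (!all(paired_ids %in% names(candidates_by_sample)))
    stop("unmatched pair id: ",
         paste(setdiff(paired_ids, names(candidates_by_sample)),
               collapse = ", "))
  if (is.null(background_samples))
    background_samples <- setdiff(names(candidates_by_sample), paired_ids)
  somatic <- NULL; lost <- NULL
  for (pi in seq_along(pairs)) {
    tumour <- pairs[[pi]][1]; normal <- pairs[[pi]][2]
    pid <- sprintf("P%04d", pi)
    tt <- candidates_by_sample[[tumour]]
    nn <- candidates_by_sample[[normal]]
    if (!is.null(tt) && nrow(tt) > 0) for (i in seq_len(nrow(tt))) {
      cand <- tt[i, ]
      if (cand$support < somatic_support) next
      if (.locus_support(cand, nn, mt_len, merge_dist) > 0) next
      if (strict) {
        bg <- vapply(background_samples, function(s)
          .locus_support(cand, candidates_by_sample[[s]], mt_len,
                         merge_dist), 0L)
        if (any(bg > 0)) next
      }
      somatic <- rbind(somatic, cbind(cand, pair = pid))
    }
    if (!is.null(nn) && nrow(nn) > 0) for (i in seq_len(nrow(nn))) {
      cand <- nn[i, ]
      if (cand$support < somatic_support) next
      if (.locus_support(cand, tt, mt_len, merge_dist) > 1) next
      lost <- rbind(lost, cbind(cand, pair = pid))
    }
  }
  empty <- cbind(.empty_candidates(), data.frame(pair = character(0)))
  list(tumour_specific = if (is.null(somatic)) empty else somatic,
       lost = if (is.null(lost)) empty else lost)
}

#' Insertion rate with exact binomial confidence interval
#'
#' The rate rho is the exact quotient events/denominator (de novo events per
#' trio, or tumour-specific events per tumour-normal pair); the 95% interval
#' is Clopper-Pearson (exact binomial, Beta-quantile form), with the lower
#' bound 0 at zero events and the upper bound 1 when events = denominator.
#'
#' @param events non-negative event count.
#' @param denominator number of opportunities (trios / genomes), >= 1.
#' @param conf confidence level (default 0.95).
#' @return list `events`, `denominator`, `rho`, `ci_low`, `ci_high`.
#' @export
insertion_rate <- function(events, denominator, conf = 0.95) {
  if (denominator < 1) stop("denominator must be >= 1")
  if (events < 0 || events > denominator)
    stop("events must lie in [0, denominator]")
  alpha <- 1 - conf
  lo <- if (events == 0) 0 else qbeta(alpha / 2, events,
                                      denominator - events + 1)
  hi <- if (events == denominator) 1 else qbeta(1 - alpha / 2, events + 1,
                                                denominator - events)
  list(events = events, denominator = denominator,
       rho = events / denominator, ci_low = lo, ci_high = hi)
}

#' 2x2 carrier association (odds ratio + Fisher exact test)
#'
#' The odds ratio is the sample estimate (a d)/(b c) (with a 0.5 continuity
#' correction when any cell is zero, noted in the result); the two-sided p
#' comes from the Fisher exact test under the probability-mass rule (sum of
#' tables as or less probable than the observed one). The reported interval
#' is the normal approximation on the log odds ratio; the conditional-MLE
#' interval of the exact test is also returned.
#'
#' @param a,b,c,d cell counts: (carrier, non-carrier) x (group 1, group 2).
#' @return list `table`, `odds_ratio`, `fisher_p`, `ci_low`, `ci_high`
#'   (log-OR normal approximation), `conditional_ci`, `continuity`.
#' @export
two_by_two_association <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("all table margins must be positive")
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  ft <- fisher.test(m)
  continuity <- any(m == 0)
  mm <- if (continuity) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  se <- sqrt(sum(1 / mm))
  list(table = m, odds_ratio = or, fisher_p = ft$p.value,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       conditional_ci = unname(ft$conf.int), continuity = continuity)
}
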