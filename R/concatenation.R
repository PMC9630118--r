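# Concatenated (mega-)NUMT evidence: split reads whose two segments both lie
# on the mitochondrial genome. Junctions are collapsed across samples,
# filtered (cohort support, per-carrier support, D-loop terminus exclusion,
# minimum separation from mtDNA-deletion-like pairs) and classified for
# parental transmission in trios.

# Realign one soft-clipped mt read as an mt-mt split: the full read is
# locally aligned to mtDNA (maximal segment), then the uncovered query
# portion is aligned again. Reads whose second segment aligns as well or
# better to the nuclear genome are rejected (only reads aligning solely to
# mtDNA evidence a concatemer; outer nuclear-mt junction reads and chance
# flank similarities are excluded). Returns NULL or
# list(pos1, pos2, sample_id) with 1-based positions, pos1 < pos2.
.mt_mt_realign <- function(read, reference, min_len = 20L,
                           min_identity = 0.9) {
  q <- read$seq
  mt <- reference$contigs[[reference$mt_name]]
  al1 <- .best_local(q, mt)
  if (is.null(al1) || al1$identity < min_identity ||
      al1$aligned_len < min_len) return(NULL)
  n <- nchar(q)
  left_rest <- al1$query_start - 1L
  right_rest <- n - al1$query_end
  if (max(left_rest, right_rest) < min_len) return(NULL)
  if (right_rest >= left_rest) {
    q2 <- substr(q, al1$query_end + 1L, n)
    first <- al1
  } else {
    q2 <- substr(q, 1L, al1$query_start - 1L)
    first <- NULL
  }
  al2 <- .best_local(q2, mt)
  if (is.null(al2) || al2$identity < min_identity ||
      al2$aligned_len < min_len) return(NULL)
  for (ctg in setdiff(names(reference$contigs), reference$mt_name)) {
    nal <- .best_local(q2, reference$contigs[[ctg]])
    if (!is.null(nal) && nal$score >= al2$score) return(NULL)
  }
  if (is.null(first)) {     # second segment covers the query prefix
    left <- al2; right <- al1
  } else {
    left <- al1; right <- al2
  }
  bound <- function(al, side) {
    if (al$strand == "+") {
      if (side == "end") al$subject_end else al$subject_start + 1L
    } else {
      if (side == "end") al$subject_start + 1L else al$subject_end
    }
  }
  a <- bound(left, "end")
  b <- bound(right, "start")
  list(pos1 = min(a, b), pos2 = max(a, b), sample_id = read$sample_id)
}

#' Detect mtDNA-mtDNA junctions across a cohort
#'
#' Collects soft-clipped reads aligned to the mitochondrial contig, realigns
#' them as two mt segments, collapses junctions within a positional
#' tolerance, and applies the filter cascade in order: (1) at least
#' `min_top_support` split reads in at least one sample; (2) per retained
#' carrier, at least `min_carrier_support` split reads; (3) both positions
#' outside the D-loop terminus exclusion windows; (4) circular distance
#' between the positions at least `min_separation` (closer pairs may be
#' mtDNA deletions).
#'
#' @param reads_by_sample named list of per-sample alignment data.frames.
#' @param reference a `numt_reference`.
#' @param min_clip minimum soft-clip length considered (default 20).
#' @param collapse_tol positional tolerance for cross-sample grouping
#'   (default 5 bp).
#' @param exclusion_windows list of `c(start, end)` 1-based inclusive mt
#'   windows near the origin (defaults: 16,470-16,569 and 1-100).
#' @param min_separation minimum circular distance between the junction
#'   positions (default 50 bp).
#' @param min_top_support,min_carrier_support cascade thresholds (3 and 2).
#' @return data.frame of junctions: `pos1`, `pos2` (1-based, pos1 < pos2),
#'   `n_carriers`, `carriers` (semicolon-joined), `total_support`; attribute
#'   `support` holds the raw per-(junction, sample) split counts before
#'   filtering (used for transmission classification).
#' @export
detect_mt_mt_junctions <- function(reads_by_sample, reference,
                                   min_clip = 20L, collapse_tol = 5L,
                                   exclusion_windows = list(c(16470, 16569),
                                                            c(1, 100)),
                                   min_separation = 50L,
                                   min_top_support = 3L,
                                   min_carrier_support = 2L) {
  obs <- NULL
  for (sid in names(reads_by_sample)) {
    r <- reads_by_sample[[sid]]
    r <- r[!is.na(r$contig) & r$contig == reference$mt_name & r$mapq > 0, ,
           drop = FALSE]
    if (nrow(r) == 0) next
    clips <- .clips_vec(r$cigar)
    r <- r[pmax(clips[, 1], clips[, 2]) >= min_clip, , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      j <- .mt_mt_realign(r[i, ], reference)
      if (!is.null(j))
        obs <- rbind(obs, data.frame(pos1 = j$pos1, pos2 = j$pos2,
                                     sample_id = sid))
    }
  }
  if (is.null(obs) || nrow(obs) == 0) {
    out <- data.frame(pos1 = integer(0), pos2 = integer(0),
                      n_carriers = integer(0), carriers = character(0),
                      total_support = integer(0))
    attr(out, "support") <- data.frame(pos1 = integer(0), pos2 = integer(0),
                                       sample_id = character(0),
                                       n_reads = integer(0))
    return(out)
  }
  # collapse within tolerance (single linkage on both coordinates)
  o <- obs[order(obs$pos1, obs$pos2), , drop = FALSE]
  gid <- integer(nrow(o))
  gid[1] <- 1L
  reps <- list(c(o$pos1[1], o$pos2[1]))
  for (i in seq_len(nrow(o))[-1]) {
    assigned <- FALSE
    for (g in seq_along(reps)) {
      if (abs(o$pos1[i] - reps[[g]][1]) <= collapse_tol &&
          abs(o$pos2[i] - reps[[g]][2]) <= collapse_tol) {
        gid[i] <- g; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps[[length(reps) + 1]] <- c(o$pos1[i], o$pos2[i])
      gid[i] <- length(reps)
    }
  }
  o$group <- gid
  support <- do.call(rbind, lapply(split(o, o$group), function(x) {
    data.frame(pos1 = .modal(x$pos1), pos2 = .modal(x$pos2),
               sample_id = names(table(x$sample_id)),
               n_reads = as.integer(table(x$sample_id)))
  }))
  rownames(support) <- NULL
  key <- paste(support$pos1, support$pos2)
  out <- NULL
  for (k in unique(key)) {
    s <- support[key == k, , drop = FALSE]
    # (1) cohort-level support
    if (max(s$n_reads) < min_top_support) next
    # (2) per-carrier support
    s <- s[s$n_reads >= min_carrier_support, , drop = FALSE]
    if (nrow(s) == 0) next
    p1 <- s$pos1[1]; p2 <- s$pos2[1]
    # (3) terminus exclusion windows
    in_win <- any(vapply(exclusion_windows, function(w)
      (p1 >= w[1] && p1 <= w[2]) || (p2 >= w[1] && p2 <= w[2]),
      logical(1)))
    if (in_win) next
    # (4) minimum separation
    if (circular_distance(p1, p2, reference$mt_length) < min_separation) next
    out <- rbind(out, data.frame(
      pos1 = p1, pos2 = p2, n_carriers = nrow(s),
      carriers = paste(sort(s$sample_id), collapse = ";"),
      total_support = sum(s$n_reads)))
  }
  if (is.null(out))
    out <- data.frame(pos1 = integer(0), pos2 = integer(0),
                      n_carriers = integer(0), carriers = character(0),
                      total_support = integer(0))
  rownames(out) <- NULL
  attr(out, "support") <- support
  out
}

#' Classify parental transmission of mt-mt junctions in trios
#'
#' A junction present in the offspring and the father but not the mother is
#' father-transmitted; the mirror case is mother-transmitted; junctions
#' present in both parents or in neither are indeterminate (child-only cases
#' are additionally flagged as candidate de novo). Presence in a parent is
#' at least one supporting split read (maximal sensitivity for excluding
#' de novo status).
#'
#' @param junctions result of [detect_mt_mt_junctions()] (its `support`
#'   attribute provides raw per-sample read counts).
#' @param manifest data.frame from [design_manifest()] (or equivalent with
#'   `sample`, `role`, `family`).
#' @param cohort_numts optional cohort call table
#'   (see [unify_cohort_numts()]); when given, rare junctions (carrier
#'   frequency < 1%) are cross-referenced for whether all their carriers
#'   share a NUMT call (`shared_numt` column).
#' @param n_samples cohort size used for the junction frequency; defaults to
#'   the number of samples in `manifest`.
#' @return data.frame: `pos1`, `pos2`, `family`, `child`, `status` in
#'   {father_transmitted, mother_transmitted, indeterminate},
#'   `de_novo_candidate`, optionally `shared_numt`.
#' @export
classify_transmission <- function(junctions, manifest, cohort_numts = NULL,
                                  n_samples = NULL) {
  support <- attr(junctions, "support")
  if (is.null(n_samples)) n_samples <- nrow(manifest)
  fams <- unique(manifest$family[manifest$role == "child"])
  out <- NULL
  for (i in seq_len(nrow(junctions))) {
    jj <- junctions[i, ]
    sup <- support[support$pos1 == jj$pos1 & support$pos2 == jj$pos2, ,
                   drop = FALSE]
    present <- function(sid) sid %in% sup$sample_id[sup$n_reads >= 1]
    for (fam in fams) {
      trio <- manifest[manifest$family == fam, ]
      child <- trio$sample[trio$role == "child"]
      father <- trio$sample[trio$role == "father"]
      mother <- trio$sample[trio$role == "mother"]
      if (length(child) != 1 || length(father) != 1 || length(mother) != 1)
        stop("family ", fam, " is not a complete trio in the manifest")
      if (!all(c(child, father, mother) %in% manifest$sample))
        stop("pedigree sample missing from cohort")
      if (!present(child)) next
      st <- if (present(father) && !present(mother)) "father_transmitted"
            else if (present(mother) && !present(father)) "mother_transmitted"
            else "indeterminate"
      out <- rbind(out, data.frame(
        pos1 = jj$pos1, pos2 = jj$pos2, family = fam, child = child,
        status = st,
        de_novo_candidate = !present(father) && !present(mother)))
    }
  }
  if (is.null(out))
    out <- data.frame(pos1 = integer(0), pos2 = integer(0),
                      family = character(0), child = character(0),
                      status = character(0), de_novo_candidate = logical(0))
  if (!is.null(cohort_numts) && nrow(out) > 0) {
    out$shared_numt <- NA
    for (i in seq_len(nrow(out))) {
      jj <- junctions[junctions$pos1 == out$pos1[i] &
                        junctions$pos2 == out$pos2[i], ]
      if (jj$n_carriers / n_samples >= 0.01) next
      carr <- strsplit(jj$carriers, ";")[[1]]
      shared <- vapply(seq_len(nrow(cohort_numts)), function(k) {
        all(carr %in% strsplit(cohort_numts$carriers[k], ";")[[1]])
      }, logical(1))
      out$shared_numt[i] <- any(shared)
    }
  }
  rownames(out) <- NULL
  out
}
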