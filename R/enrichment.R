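# Permutation enrichment of NUMT positions against annotation tracks,
# mtDNA-region enrichment on the circular genome, deletion-breakpoint
# window correlation, nearest-feature distances, and the per-chromosome
# count regression.

# Merge an interval set (0-based half-open) into disjoint sorted intervals.
.merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  if (nrow(iv) > 1) for (i in seq(2, nrow(iv))) {
    k <- length(out_s)
    if (iv$start[i] <= out_e[k]) out_e[k] <- max(out_e[k], iv$end[i])
    else { out_s <- c(out_s, iv$start[i]); out_e <- c(out_e, iv$end[i]) }
  }
  data.frame(start = out_s, end = out_e)
}

# Overlap indicator of [f1, f2) windows against merged disjoint intervals.
.window_hits <- function(f1, f2, merged) {
  if (nrow(merged) == 0) return(rep(FALSE, length(f1)))
  i <- findInterval(f2 - 1L, merged$start)
  ok <- i >= 1
  ok[ok] <- merged$end[i[ok]] > f1[ok]
  ok
}

# Two-tailed empirical p with the add-one rule, doubled and capped at 1.
.perm_p <- function(observed, null_counts) {
  n <- length(null_counts)
  r_ge <- sum(null_counts >= observed)
  r_le <- sum(null_counts <= observed)
  p <- 2 * (1 + min(r_ge, r_le)) / (n + 1)
  min(1, p)
}

#' Permutation enrichment of NUMT positions in an annotation track
#'
#' The observed statistic is the number of NUMTs whose +/- `flank` bp window
#' around the nuclear position intersects the track. Each of `n_perm` null
#' replicates places the same number of positions uniformly on the same
#' chromosome as the corresponding observed NUMT (count-and-chromosome
#' matching), excluding the mitochondrial contig and any contig in
#' `exclude`. The two-tailed empirical p uses the add-one rule
#' (never below 2/(n_perm + 1)), doubled and capped at 1.
#'
#' @param positions data.frame with `contig` and `pos` (1-based nuclear
#'   positions, e.g. insertion breakpoints).
#' @param track an `interval_track` on the nuclear genome.
#' @param reference a `numt_reference`.
#' @param n_perm replicates (>= 100; default 1,000).
#' @param seed RNG seed; results are reproducible given (seed, n_perm).
#' @param flank half-width of the window (default 100 bp, a 200 bp flank).
#' @param exclude contig names never used (Y chromosome convention).
#' @return list: `track`, `observed`, `null_counts`, `empirical_p`,
#'   `direction` (enriched/depleted), `n`, `seed`.
#' @export
permutation_enrichment <- function(positions, track, reference,
                                   n_perm = 1000L, seed = 1L, flank = 100L,
                                   exclude = "chrY") {
  if (n_perm < 100) stop("n_perm must be >= 100")
  drop <- positions$contig %in% c(reference$mt_name, exclude)
  positions <- positions[!drop, , drop = FALSE]
  n <- nrow(positions)
  merged_by_ctg <- lapply(split(track$intervals,
                                track$intervals$contig), .merge_intervals)
  if (sum(vapply(merged_by_ctg, nrow, 0L)) == 0 || n == 0) {
    return(list(track = track$name, observed = NA_integer_,
                null_counts = rep(NA_integer_, n_perm),
                empirical_p = NA_real_, direction = NA_character_, n = n,
                seed = seed))
  }
  hit_one <- function(ctg, p0) {
    mg <- merged_by_ctg[[ctg]]
    if (is.null(mg)) rep(FALSE, length(p0))
    else .window_hits(pmax(p0 - flank, 0L), p0 + flank + 1L, mg)
  }
  p0 <- positions$pos - 1L
  observed <- 0L
  for (ctg in unique(positions$contig)) {
    sel <- positions$contig == ctg
    observed <- observed + sum(hit_one(ctg, p0[sel]))
  }
  null_counts <- .with_seed(seed, {
    nc <- integer(n_perm)
    for (ctg in unique(positions$contig)) {
      k <- sum(positions$contig == ctg)
      L <- nchar(reference$contigs[[ctg]])
      draws <- matrix(floor(runif(n_perm * k, 0, L)), nrow = n_perm)
      hits <- matrix(hit_one(ctg, as.vector(draws)), nrow = n_perm)
      nc <- nc + rowSums(hits)
    }
    nc
  })
  p <- .perm_p(observed, null_counts)
  direction <- if (observed >= mean(null_counts)) "enriched" else "depleted"
  list(track = track$name, observed = observed, null_counts = null_counts,
       empirical_p = p, direction = direction, n = n, seed = seed)
}

#' mtDNA region enrichment of breakpoints on the circular genome
#'
#' Same permutation contract as [permutation_enrichment()], with null
#' positions uniform on 1..mt_length and regions taken from the packaged
#' (or user-supplied) region table, circular-aware.
#'
#' @param mt_positions integer vector of 1-based mt breakpoint positions.
#' @param reference a `numt_reference`.
#' @param regions region table (see [mt_region_table()]); protein, rRNA and
#'   control regions are tested individually, the 22 tRNAs as one combined
#'   region.
#' @param n_perm,seed permutation parameters.
#' @return data.frame: `region`, `observed`, `expected`, `empirical_p`,
#'   `direction`.
#' @export
mt_region_enrichment <- function(mt_positions, reference,
                                 regions = mt_region_table(),
                                 n_perm = 1000L, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  L <- reference$mt_length
  need <- c("D-loop", "HV1", "HV2", "HV3", "OH", "OL")
  if (!all(need %in% regions$region))
    stop("configuration error: region table missing ",
         paste(setdiff(need, regions$region), collapse = ", "))
  # membership masks; tRNAs are combined into one region
  groups <- split(regions, ifelse(regions$type == "tRNA", "tRNA_combined",
                                  regions$region))
  masks <- lapply(groups, function(g) {
    m <- logical(L)
    for (i in seq_len(nrow(g))) {
      if (g$end[i] >= g$start[i]) m[g$start[i]:g$end[i]] <- TRUE
      else m[c(g$start[i]:L, 1:g$end[i])] <- TRUE    # wraps the origin
    }
    m
  })
  n <- length(mt_positions)
  null_pos <- .with_seed(seed, matrix(sample.int(L, n_perm * n,
                                                 replace = TRUE),
                                      nrow = n_perm))
  do.call(rbind, lapply(names(masks), function(rg) {
    m <- masks[[rg]]
    obs <- sum(m[mt_positions])
    nulls <- rowSums(matrix(m[null_pos], nrow = n_perm))
    data.frame(region = rg, observed = obs, expected = mean(nulls),
               empirical_p = .perm_p(obs, nulls),
               direction = if (obs >= mean(nulls)) "enriched" else "depleted")
  }))
}

#' Windowed correlation of NUMT and deletion breakpoints on mtDNA
#'
#' Both breakpoint sets are binned into fixed windows along the
#' mitochondrial genome (166 windows of 100 bp at the rCRS length) and the
#' per-window frequencies are compared by Pearson correlation.
#'
#' @param numt_positions,deletion_positions 1-based mt positions.
#' @param mt_length genome length.
#' @param window window size in bp (default 100).
#' @return list `r`, `r_squared`, `p`, `n_windows`; NA when either binned
#'   vector is all zero.
#' @export
breakpoint_window_correlation <- function(numt_positions, deletion_positions,
                                          mt_length, window = 100L) {
  nb <- ceiling(mt_length / window)
  bin <- function(p) tabulate(pmin((p - 1L) %/% window + 1L, nb), nbins = nb)
  x <- bin(numt_positions); y <- bin(deletion_positions)
  if (sum(x) == 0 || sum(y) == 0 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n_windows = nb))
  ct <- cor.test(x / sum(x), y / sum(y), method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n_windows = nb)
}

#' Distance from NUMT positions to the nearest track feature
#'
#' Per NUMT, the minimum absolute distance from the nuclear breakpoint to
#' any interval of the track on the same chromosome (0 when inside);
#' chromosomes without features yield an infinite sentinel, excluded from
#' summaries with their count reported. Threshold counts come with a
#' permutation p for the "within d" indicator, reusing the
#' count-and-chromosome-matched null.
#'
#' @param positions data.frame `contig`, `pos` (1-based).
#' @param track an `interval_track`.
#' @param reference a `numt_reference`.
#' @param thresholds distances of interest (default 1 kb and 3 kb).
#' @param n_perm,seed permutation parameters.
#' @return list: `distances` (per-NUMT data.frame), `summary` (per
#'   threshold: count within, permutation p, direction), `n_no_feature`.
#' @export
distance_to_nearest_feature <- function(positions, track, reference,
                                        thresholds = c(1000L, 3000L),
                                        n_perm = 1000L, seed = 1L) {
  merged_by_ctg <- lapply(split(track$intervals,
                                track$intervals$contig), .merge_intervals)
  dist_one <- function(ctg, p0) {
    mg <- merged_by_ctg[[ctg]]
    if (is.null(mg) || nrow(mg) == 0) return(rep(Inf, length(p0)))
    vapply(p0, function(p) {
      inside <- any(mg$start <= p & mg$end > p)
      if (inside) return(0)
      min(abs(c(mg$start - p, p - (mg$end - 1L))))
    }, 0)
  }
  d <- numeric(nrow(positions))
  for (ctg in unique(positions$contig)) {
    sel <- positions$contig == ctg
    d[sel] <- dist_one(ctg, positions$pos[sel] - 1L)
  }
  scored <- is.finite(d)
  summary_tab <- do.call(rbind, lapply(thresholds, function(th) {
    obs <- sum(d[scored] <= th)
    nulls <- .with_seed(seed + th, {
      nc <- integer(n_perm)
      for (ctg in unique(positions$contig[scored])) {
        k <- sum(positions$contig == ctg & scored)
        L <- nchar(reference$contigs[[ctg]])
        draws <- matrix(floor(runif(n_perm * k, 0, L)) + 1L, nrow = n_perm)
        dm <- matrix(dist_one(ctg, as.vector(draws) - 1L), nrow = n_perm)
        nc <- nc + rowSums(dm <= th)
      }
      nc
    })
    data.frame(threshold = th, within = obs, expected = mean(nulls),
               empirical_p = .perm_p(obs, nulls),
               direction = if (obs >= mean(nulls)) "enriched" else "depleted")
  }))
  list(distances = data.frame(positions, distance = d),
       summary = summary_tab, n_no_feature = sum(!scored))
}

#' Per-chromosome NUMT count regression
#'
#' Ordinary least squares of the per-chromosome NUMT count on chromosome
#' length and eleven log2-transformed genomic-feature proportions
#' (centromere, CpG islands, LINEs, LTRs, retroposons, SINEs,
#' microsatellites, repeat-masked, simple repeats, duplications, regulatory
#' elements). The chromosome-length coefficient's p-value is the headline
#' length association.
#'
#' @param input data.frame with columns `Nnumt`, `Lchr`, `Pcentro`, `Pcpg`,
#'   `Pline`, `Pltr`, `Pretroposon`, `Psine`, `Pmicrosat`, `Prmsk`,
#'   `Prepeats`, `Pdups`, `Preg` (proportions already log2-transformed).
#' @return list: `coefficients` (estimate, std.error, t, p per term),
#'   `r_squared`, `length_p` (p for `Lchr`), `n`.
#' @export
chromosome_count_model <- function(input) {
  preds <- c("Lchr", "Pcentro", "Pcpg", "Pline", "Pltr", "Pretroposon",
             "Psine", "Pmicrosat", "Prmsk", "Prepeats", "Pdups", "Preg")
  miss <- setdiff(c("Nnumt", preds), names(input))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(input) < length(preds) + 2)
    stop("need at least ", length(preds) + 2, " chromosomes")
  X <- as.matrix(input[, preds])
  qr_x <- qr(cbind(1, X))
  if (qr_x$rank < ncol(X) + 1) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    stop("rank-deficient design; collinear column(s): ",
         paste(preds[dropped[dropped > 0]], collapse = ", "))
  }
  fml <- stats::as.formula(paste("Nnumt ~", paste(preds, collapse = " + ")))
  fit <- lm(fml, data = input)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "std.error", "t", "p")
  co$term <- rownames(co)
  rownames(co) <- NULL
  list(coefficients = co[, c("term", "estimate", "std.error", "t", "p")],
       r_squared = sm$r.squared, length_p = co$p[co$term == "Lchr"],
       n = nrow(input))
}
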