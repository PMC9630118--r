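# Molecular evolution of NUMT sequences: greedy overlap-layout consensus
# assembly per (NUMT, sample), post-insertion variant calling with the
# ordered filter cascade, coding effects under the vertebrate mitochondrial
# genetic code, 96-class pyrimidine-centred mutational spectra, and
# ancestral-allele-ratio age estimation against a chimpanzee ancestral
# mitochondrial sequence.

# rCRS low-complexity regions excluded from mt variant calling (1-based).
MT_LOW_COMPLEXITY <- list(c(66, 71), c(300, 316), c(513, 525),
                          c(3106, 3107), c(12418, 12425), c(16182, 16194))

# 1-based mt positions of a fragment stored as a 0-based half-open span
# (wrapping when mt_end <= mt_start).
.fragment_positions <- function(mt_start0, mt_end0, L) {
  if (mt_end0 > mt_start0) seq(mt_start0 + 1L, mt_end0)
  else c(seq(mt_start0 + 1L, L), seq_len(mt_end0))
}

# max k >= min_k with suffix(a, k) == prefix(b, k); 0 if none.
# Seeded: occurrences of b's min_k-prefix inside a pin the only candidate
# overlap lengths, so the full comparison runs at most a handful of times.
.max_overlap <- function(a, b, min_k) {
  na <- nchar(a); nb <- nchar(b)
  if (min(na, nb) < min_k) return(0L)
  seed <- substr(b, 1L, min_k)
  hits <- gregexpr(seed, a, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(0L)
  ks <- na - hits + 1L
  ks <- sort(ks[ks >= min_k & ks <= min(na, nb)], decreasing = TRUE)
  for (k in ks) {
    if (substr(a, na - k + 1L, na) == substr(b, 1L, k)) return(k)
  }
  0L
}

# column-majority consensus over a layout; ties yield "N" and the tied
# column indices are reported
.layout_consensus <- function(seqs, weights, layout) {
  layout$offset <- layout$offset - min(layout$offset)
  span <- max(layout$offset + nchar(seqs[layout$idx]))
  alpha <- c("A", "C", "G", "T", "N")
  votes <- matrix(0, nrow = 5, ncol = span)
  for (i in seq_len(nrow(layout))) {
    s <- strsplit(seqs[layout$idx[i]], "")[[1]]
    bi <- match(s, alpha)
    cols <- layout$offset[i] + seq_along(s)
    ix <- cbind(bi, cols)
    votes[ix] <- votes[ix] + weights[layout$idx[i]]
  }
  v <- votes[1:4, , drop = FALSE]
  mx <- apply(v, 2, max)
  top1 <- apply(v, 2, which.max)
  n_top <- colSums(v == rep(mx, each = 4))
  cons <- ifelse(mx == 0, "N", alpha[top1])
  tied <- which(mx > 0 & n_top > 1)
  list(seq = paste(cons, collapse = ""), tied = tied)
}

#' Greedy overlap-layout consensus assembly
#'
#' Iteratively merges the pair of contigs with the longest exact
#' suffix-prefix overlap at or above `min_overlap` (ties resolved to the
#' lexicographically smaller merged string); base calls are column
#' majorities over all placed reads. Contigs that never reach an exact
#' overlap are placed onto the largest contig by a mismatch-tolerant scan
#' (at most 10% mismatches) so that minority alleles still vote; if no
#' placement exists the assembly is flagged fragmented and the largest
#' contig is returned. Exact 50-50 column ties resolve to the reference
#' base when `ref_fragment` is supplied (N otherwise).
#'
#' @param seqs read sequences (all in the same orientation).
#' @param min_overlap minimum exact overlap (default 25 bp).
#' @param ref_fragment optional reference sequence used to resolve ties.
#' @return list: `consensus`, `n_reads`, `fragmented`, `n_contigs`.
#' @export
assemble_numt_consensus <- function(seqs, min_overlap = 25L,
                                    ref_fragment = NULL) {
  if (length(seqs) < 2) stop("need at least 2 reads")
  tab <- table(seqs)
  useqs <- names(tab)
  weights <- as.integer(tab)
  n <- length(useqs)
  contigs <- lapply(seq_len(n), function(i)
    list(seq = useqs[i], layout = data.frame(idx = i, offset = 0L)))
  # cached overlap matrix; only rows/columns touching a merge are refreshed
  ovm <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j)
      ovm[i, j] <- .max_overlap(contigs[[i]]$seq, contigs[[j]]$seq,
                                min_overlap)
  }
  alive <- rep(TRUE, n)
  repeat {
    if (sum(alive) == 1) break
    best_k <- max(ovm[alive, alive, drop = FALSE])
    if (best_k < min_overlap) break
    idx <- which(ovm == best_k & outer(alive, alive, `&`), arr.ind = TRUE)
    merge_one <- function(pr) {
      i <- pr[1]; j <- pr[2]
      off <- nchar(contigs[[i]]$seq) - best_k
      lay <- rbind(contigs[[i]]$layout,
                   transform(contigs[[j]]$layout, offset = offset + off))
      cons <- .layout_consensus(useqs, weights, lay)
      list(seq = cons$seq, layout = lay)
    }
    merged <- if (nrow(idx) == 1) list(merge_one(idx[1, ]))
              else lapply(seq_len(nrow(idx)), function(r) merge_one(idx[r, ]))
    pick <- order(vapply(merged, `[[`, "", "seq"))[1]
    i <- idx[pick, 1]; j <- idx[pick, 2]
    contigs[[i]] <- merged[[pick]]
    alive[j] <- FALSE
    ovm[j, ] <- 0L; ovm[, j] <- 0L
    for (k in which(alive)) {
      if (k == i) next
      ovm[i, k] <- .max_overlap(contigs[[i]]$seq, contigs[[k]]$seq,
                                min_overlap)
      ovm[k, i] <- .max_overlap(contigs[[k]]$seq, contigs[[i]]$seq,
                                min_overlap)
    }
  }
  contigs <- contigs[alive]
  fragmented <- length(contigs) > 1
  if (fragmented) {
    # mismatch-tolerant placement onto the largest contig
    sizes <- vapply(contigs, function(ct) nchar(ct$seq), 0L)
    main <- which.max(sizes)
    others <- setdiff(seq_along(contigs), main)
    placed_any <- FALSE
    for (j in others) {
      a <- contigs[[main]]$seq; b <- contigs[[j]]$seq
      na <- nchar(a); nb <- nchar(b)
      best <- NULL
      for (off in seq(-nb + min_overlap, na - min_overlap)) {
        lo <- max(0L, off); hi <- min(na, off + nb)
        if (hi - lo < min_overlap) next
        sa <- substr(a, lo + 1L, hi)
        sb <- substr(b, lo - off + 1L, hi - off)
        mm <- sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
        if (mm <= 0.1 * (hi - lo) && (is.null(best) || mm < best$mm))
          best <- list(off = off, mm = mm)
      }
      if (!is.null(best)) {
        contigs[[main]]$layout <- rbind(
          contigs[[main]]$layout,
          transform(contigs[[j]]$layout, offset = offset + best$off))
        placed_any <- TRUE
      }
    }
    if (placed_any) {
      cons <- .layout_consensus(useqs, weights, contigs[[main]]$layout)
      contigs[[main]]$seq <- cons$seq
    }
    contigs <- contigs[main]
    fragmented <- !placed_any && fragmented
  }
  final <- .layout_consensus(useqs, weights, contigs[[1]]$layout)
  cons <- final$seq
  if (length(final$tied) > 0 && !is.null(ref_fragment)) {
    al <- .best_local(cons, ref_fragment)
    if (!is.null(al) && al$strand == "+") {
      for (c_ in final$tied) {
        if (c_ >= al$query_start && c_ <= al$query_end) {
          rp <- al$subject_start + (c_ - al$query_start) + 1L
          substr(cons, c_, c_) <- substr(ref_fragment, rp, rp)
        }
      }
    }
  }
  list(consensus = cons, n_reads = length(seqs),
       fragmented = fragmented, n_contigs = 1L)
}

# Collect insert-derived sequences for one cohort NUMT in one sample: the
# aligned (M) portions of mt-mapped reads within the fragment span, all in
# mt-forward orientation.
.insert_read_seqs <- function(reads, cohort_row, reference, margin = 50L) {
  r <- reads[!is.na(reads$contig) & reads$contig == reference$mt_name &
               reads$mapq > 0, , drop = FALSE]
  if (nrow(r) == 0) return(character(0))
  clips <- .clips_vec(r$cigar)
  # reference span; indel-free cigars dominate, the rest via full parsing
  ref_len <- nchar(r$seq) - clips[, 1] - clips[, 2]
  indel <- grepl("[ID]", r$cigar)
  if (any(indel))
    ref_len[indel] <- vapply(r$cigar[indel], cigar_reference_length, 0L)
  # vectorized circular gap between the fragment span and each read span
  L <- reference$mt_length
  fs <- cohort_row$mt_start; fe <- cohort_row$mt_end
  if (fe < fs) fe <- fe + L
  rs <- r$start; re <- r$start + ref_len
  gap <- rep(Inf, nrow(r))
  for (sh in c(-L, 0L, L)) {
    g <- pmax(0, pmax(fs, rs + sh) - pmin(fe, re + sh))
    gap <- pmin(gap, g)
  }
  keep <- gap <= margin
  r <- r[keep, , drop = FALSE]
  cl <- clips[keep, , drop = FALSE]
  substr(r$seq, cl[, 1] + 1L, nchar(r$seq) - cl[, 2])
}

#' Assemble consensus sequences for cohort NUMTs
#'
#' Runs [assemble_numt_consensus()] for every (cohort NUMT, carrier) with at
#' least two insert-derived reads.
#'
#' @param reads_by_sample named list of per-sample alignments.
#' @param cohort cohort table (see [unify_cohort_numts()]).
#' @param reference a `numt_reference`.
#' @param min_overlap assembly overlap threshold.
#' @return data.frame: `cohort_numt_id`, `sample_id`, `consensus`,
#'   `n_reads`, `fragmented`.
#' @export
assemble_cohort_consensus <- function(reads_by_sample, cohort, reference,
                                      min_overlap = 25L) {
  out <- NULL
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    fp <- .fragment_positions(row$mt_start, row$mt_end, reference$mt_length)
    frag <- mt_fragment(reference, fp[1], fp[length(fp)])
    for (sid in strsplit(row$carriers, ";")[[1]]) {
      seqs <- .insert_read_seqs(reads_by_sample[[sid]], row, reference)
      if (length(seqs) < 2) next
      asm <- assemble_numt_consensus(seqs, min_overlap = min_overlap,
                                     ref_fragment = frag)
      out <- rbind(out, data.frame(
        cohort_numt_id = row$cohort_numt_id, sample_id = sid,
        consensus = asm$consensus, n_reads = asm$n_reads,
        fragmented = asm$fragmented))
    }
  }
  if (is.null(out))
    out <- data.frame(cohort_numt_id = character(0), sample_id = character(0),
                      consensus = character(0), n_reads = integer(0),
                      fragmented = logical(0))
  out
}

# Align a consensus to the mt fragment (ends-free, gaps forbidden) and
# return the per-site consensus base over the fragment's 1-based mt
# positions (NA where uncovered).
.consensus_profile <- function(consensus, reference, mt_start0, mt_end0) {
  L <- reference$mt_length
  pos <- .fragment_positions(mt_start0, mt_end0, L)
  frag <- mt_fragment(reference, pos[1], pos[length(pos)])
  al <- .best_local(consensus, frag)
  prof <- rep(NA_character_, length(pos))
  if (is.null(al) || al$identity < 0.8 || al$strand != "+") return(prof)
  qs <- al$query_start; ss <- al$subject_start   # ss is 0-based in frag
  len <- al$query_end - qs + 1L
  bases <- strsplit(substr(consensus, qs, al$query_end), "")[[1]]
  idx <- ss + seq_len(len)
  keep <- idx <= length(pos)
  prof[idx[keep]] <- bases[keep]
  prof
}

#' Variants of a consensus against the mt reference fragment
#'
#' @param consensus assembled consensus sequence.
#' @param reference a `numt_reference`.
#' @param mt_start0,mt_end0 fragment span, 0-based half-open (wrapping when
#'   `mt_end0 <= mt_start0`).
#' @return data.frame `mt_pos` (1-based), `ref`, `alt` (SNVs only).
#' @export
consensus_variants <- function(consensus, reference, mt_start0, mt_end0) {
  L <- reference$mt_length
  pos <- .fragment_positions(mt_start0, mt_end0, L)
  prof <- .consensus_profile(consensus, reference, mt_start0, mt_end0)
  mt <- reference$contigs[[reference$mt_name]]
  ref_b <- vapply(pos, function(p) substr(mt, p, p), character(1))
  diff <- !is.na(prof) & prof != ref_b & prof != "N"
  data.frame(mt_pos = pos[diff], ref = ref_b[diff], alt = prof[diff])
}

#' Call NUMT-internal variants with the ordered filter cascade
#'
#' Filters, in order: (1) only NUMTs shorter than `max_size` bp; (2)
#' variants more than `bp_margin` bp from both fragment breakpoints; (3)
#' aligned reference allele must equal the mt reference at the position; (4)
#' single-nucleotide variants only (structural by construction); (5)
#' carriers with an outlying variant count (> cohort mean + 3 sd) dropped.
#' Variants inside the packaged mt low-complexity regions are also removed.
#' Surviving variants aggregate per cohort NUMT with carrier fractions.
#'
#' @param consensus_tab data.frame from [assemble_cohort_consensus()].
#' @param cohort cohort table.
#' @param reference a `numt_reference`.
#' @param max_size NUMT size cap (default 1,000 bp, exclusive).
#' @param bp_margin breakpoint exclusion margin (default 5 bp).
#' @param low_complexity list of 1-based mt ranges to exclude
#'   (default the packaged rCRS-convention list; `NULL` disables).
#' @return data.frame: `cohort_numt_id`, `mt_pos`, `ref`, `alt`,
#'   `carrier_count`, `carrier_fraction`, `carriers`.
#' @export
call_numt_variants <- function(consensus_tab, cohort, reference,
                               max_size = 1000L, bp_margin = 5L,
                               low_complexity = MT_LOW_COMPLEXITY) {
  L <- reference$mt_length
  per_carrier <- NULL
  for (i in seq_len(nrow(consensus_tab))) {
    ct <- consensus_tab[i, ]
    row <- cohort[cohort$cohort_numt_id == ct$cohort_numt_id, ]
    if (nrow(row) != 1) next
    if (row$size_bp >= max_size) next                         # filter (1)
    v <- consensus_variants(ct$consensus, reference, row$mt_start,
                            row$mt_end)
    if (nrow(v) == 0) next
    bp1 <- row$mt_start + 1L; bp2 <- row$mt_end                # 1-based ends
    d1 <- circular_distance(v$mt_pos, bp1, L)
    d2 <- circular_distance(v$mt_pos, bp2, L)
    v <- v[d1 > bp_margin & d2 > bp_margin, , drop = FALSE]    # filter (2)
    if (nrow(v) == 0) next
    mt <- reference$contigs[[reference$mt_name]]
    conc <- vapply(seq_len(nrow(v)), function(k)
      substr(mt, v$mt_pos[k], v$mt_pos[k]) == v$ref[k], logical(1))
    v <- v[conc, , drop = FALSE]                               # filter (3)
    v <- v[nchar(v$ref) == 1 & nchar(v$alt) == 1 &
             v$alt %in% BASES, , drop = FALSE]                 # filter (4)
    if (!is.null(low_complexity) && nrow(v) > 0) {
      bad <- vapply(v$mt_pos, function(p)
        any(vapply(low_complexity, function(r)
          p >= r[1] && p <= r[2], logical(1))), logical(1))
      v <- v[!bad, , drop = FALSE]
    }
    if (nrow(v) == 0) next
    per_carrier <- rbind(per_carrier, cbind(
      data.frame(cohort_numt_id = ct$cohort_numt_id,
                 sample_id = ct$sample_id), v))
  }
  if (is.null(per_carrier))
    return(data.frame(cohort_numt_id = character(0), mt_pos = integer(0),
                      ref = character(0), alt = character(0),
                      carrier_count = integer(0),
                      carrier_fraction = numeric(0), carriers = character(0)))
  # filter (5): per-sample outlier exclusion on variant counts
  counts <- table(per_carrier$sample_id)
  thr <- mean(counts) + 3 * sd(counts)
  if (!is.na(thr)) {
    keep_samples <- names(counts)[counts <= thr]
    per_carrier <- per_carrier[per_carrier$sample_id %in% keep_samples, ,
                               drop = FALSE]
  }
  key <- paste(per_carrier$cohort_numt_id, per_carrier$mt_pos,
               per_carrier$ref, per_carrier$alt)
  agg <- do.call(rbind, lapply(split(per_carrier, key), function(x) {
    nid <- x$cohort_numt_id[1]
    n_carr <- length(strsplit(
      cohort$carriers[cohort$cohort_numt_id == nid], ";")[[1]])
    data.frame(cohort_numt_id = nid, mt_pos = x$mt_pos[1], ref = x$ref[1],
               alt = x$alt[1], carrier_count = nrow(x),
               carrier_fraction = nrow(x) / n_carr,
               carriers = paste(sort(x$sample_id), collapse = ";"))
  }))
  agg <- agg[order(agg$cohort_numt_id, agg$mt_pos), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Classify variants into NUMT-specific groups A, B, C
#'
#' Step (1): exclude variants present in more than 50% of the carriers of
#' common or rare NUMTs, or more than 75% of the carriers of ultra-rare
#' NUMTs (those likely predate insertion); survivors are NUMT-specific and
#' form total group A. Step (2): subgroup B removes singletons (variants in
#' one individual). Step (3): subgroup C keeps variants seen in at least
#' two members of the same family.
#'
#' @param variants data.frame from [call_numt_variants()].
#' @param cohort annotated cohort table (needs `freq_class`).
#' @param manifest manifest with `sample`, `family`.
#' @return `variants` with logical `numt_specific`, `in_A`, `in_B`, `in_C`
#'   and a `group` column (deepest subgroup, NA when not NUMT-specific).
#' @export
classify_variant_groups <- function(variants, cohort, manifest) {
  if (nrow(variants) == 0) {
    variants$numt_specific <- logical(0); variants$in_A <- logical(0)
    variants$in_B <- logical(0); variants$in_C <- logical(0)
    variants$group <- character(0)
    return(variants)
  }
  fc <- cohort$freq_class[match(variants$cohort_numt_id,
                                cohort$cohort_numt_id)]
  cap <- ifelse(fc == "ultra_rare", 0.75, 0.5)
  variants$numt_specific <- variants$carrier_fraction <= cap
  variants$in_A <- variants$numt_specific
  variants$in_B <- variants$in_A & variants$carrier_count >= 2
  variants$in_C <- variants$in_B & vapply(seq_len(nrow(variants)),
    function(i) {
      if (!variants$in_B[i]) return(FALSE)
      carr <- strsplit(variants$carriers[i], ";")[[1]]
      fam <- manifest$family[match(carr, manifest$sample)]
      any(table(fam) >= 2)
    }, logical(1))
  variants$group <- ifelse(variants$in_C, "C",
                           ifelse(variants$in_B, "B",
                                  ifelse(variants$in_A, "A", NA)))
  variants
}

# the 96 COSMIC-convention class names, pyrimidine-centred
.spectrum_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (l in BASES) for (r in BASES)
      out <- c(out, sprintf("%s[%s]%s", l, s, r))
  }
  out
}

#' Coding effect and 96-class mutational spectrum of NUMT variants
#'
#' Variants inside protein-coding mt regions are classified synonymous /
#' non-synonymous by codon lookup under the vertebrate mitochondrial genetic
#' code, strand-aware; variants elsewhere get effect NA. All SNVs are
#' tallied into the 96 pyrimidine-centred trinucleotide classes
#' (purine-reference variants are reverse-complemented first). An optional
#' signature matrix (96 rows) yields cosine similarities per column.
#'
#' @param variants data.frame with `mt_pos`, `ref`, `alt`.
#' @param reference a `numt_reference`.
#' @param regions mt region table (see [mt_region_table()]).
#' @param signatures optional numeric matrix (96 x k, rownames the class
#'   labels).
#' @return list: `effects` (variants + `gene`, `effect`), `spectrum` (named
#'   96-vector), `cosine` (named numeric or NULL).
#' @export
coding_effect_and_spectrum <- function(variants, reference,
                                       regions = mt_region_table(),
                                       signatures = NULL) {
  mt <- reference$contigs[[reference$mt_name]]
  L <- reference$mt_length
  code <- Biostrings::getGeneticCode("2")    # vertebrate mitochondrial
  prot <- regions[regions$type == "protein", , drop = FALSE]
  eff <- character(nrow(variants)); gene <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    p <- variants$mt_pos[i]
    hit <- which(prot$start <= p & prot$end >= p)
    if (length(hit) == 0) { eff[i] <- NA_character_; next }
    g <- prot[hit[1], ]
    gene[i] <- g$region
    if (g$strand == "+") {
      cds_pos <- p - g$start + 1L
      codon_i <- (cds_pos - 1L) %/% 3L
      cstart <- g$start + codon_i * 3L
      if (cstart + 2L > g$end) { eff[i] <- NA_character_; next }
      codon <- substr(mt, cstart, cstart + 2L)
      off <- p - cstart + 1L
      alt_codon <- codon
      substr(alt_codon, off, off) <- variants$alt[i]
    } else {
      cds_pos <- g$end - p + 1L
      codon_i <- (cds_pos - 1L) %/% 3L
      cend <- g$end - codon_i * 3L
      if (cend - 2L < g$start) { eff[i] <- NA_character_; next }
      codon <- revcomp(substr(mt, cend - 2L, cend))
      off <- cend - p + 1L
      alt_codon <- codon
      substr(alt_codon, off, off) <- revcomp(variants$alt[i])
    }
    eff[i] <- if (code[[codon]] == code[[alt_codon]]) "synonymous"
              else "non_synonymous"
  }
  cls <- .spectrum_classes()
  spectrum <- setNames(numeric(96), cls)
  for (i in seq_len(nrow(variants))) {
    p <- variants$mt_pos[i]
    ref_b <- variants$ref[i]; alt_b <- variants$alt[i]
    lo <- ((p - 2L) %% L) + 1L
    hi <- (p %% L) + 1L
    left <- substr(mt, lo, lo); right <- substr(mt, hi, hi)
    if (ref_b %in% c("A", "G")) {
      tmp <- revcomp(left); left <- revcomp(right); right <- tmp
      ref_b <- revcomp(ref_b); alt_b <- revcomp(alt_b)
    }
    key <- sprintf("%s[%s>%s]%s", left, ref_b, alt_b, right)
    spectrum[key] <- spectrum[key] + 1
  }
  cosine <- NULL
  if (!is.null(signatures)) {
    sig <- as.matrix(signatures)
    if (nrow(sig) != 96) stop("signature matrix must have 96 rows")
    if (!is.null(rownames(sig))) sig <- sig[cls, , drop = FALSE]
    cosine <- apply(sig, 2, function(s) {
      den <- sqrt(sum(spectrum^2)) * sqrt(sum(s^2))
      if (den == 0) NA_real_ else sum(spectrum * s) / den
    })
  }
  list(effects = cbind(variants, gene = gene, effect = eff),
       spectrum = spectrum, cosine = cosine)
}

#' Estimate NUMT ages from ancestral-allele ratios
#'
#' For each NUMT, informative sites are fragment positions where the human
#' and ancestral (chimpanzee) mitochondrial sequences differ. Each carrier's
#' consensus classifies each site as matching the human or the ancestral
#' allele; a site is accepted when more than half of the carriers agree on
#' one classification. r is the fraction of accepted sites matching the
#' human allele and the age is (1 - r) x `t_div` (mutations accrue
#' uniformly on the human mtDNA lineage after divergence, so a NUMT frozen
#' at insertion time retains the ancestral allele at changes that postdate
#' it). Filters: fragment length in `size_range`; at least one informative
#' site; at least 2 carriers with consensus; concatenated NUMTs excluded.
#'
#' @param consensus_tab data.frame from [assemble_cohort_consensus()].
#' @param cohort cohort table.
#' @param reference a `numt_reference`.
#' @param chimp_mt ancestral mt sequence aligned 1:1 with the reference mt.
#' @param t_div divergence time in Myr (default 6).
#' @param size_range inclusive fragment length bounds (default 50-1,000 bp).
#' @param concatenated_ids cohort NUMT ids to exclude as concatenated.
#' @return data.frame: `cohort_numt_id`, `n_informative`, `n_match_human`,
#'   `r`, `age_myr`, `n_carriers_used`.
#' @export
estimate_numt_age <- function(consensus_tab, cohort, reference,
                              chimp_mt = synthetic_chimp_mt(),
                              t_div = 6, size_range = c(50L, 1000L),
                              concatenated_ids = character(0)) {
  L <- reference$mt_length
  human <- reference$contigs[[reference$mt_name]]
  info_all <- informative_sites(human, chimp_mt)
  out <- NULL
  for (nid in unique(consensus_tab$cohort_numt_id)) {
    row <- cohort[cohort$cohort_numt_id == nid, ]
    if (nrow(row) != 1) next
    if (nid %in% concatenated_ids) next                       # filter (4)
    if (row$size_bp < size_range[1] || row$size_bp > size_range[2]) next
    pos <- .fragment_positions(row$mt_start, row$mt_end, L)
    info <- intersect(info_all, pos)
    if (length(info) == 0) next                               # filter (2)
    cons <- consensus_tab[consensus_tab$cohort_numt_id == nid, ,
                          drop = FALSE]
    if (nrow(cons) < 2) next                                  # filter (3)
    # per-carrier site classification: human / ancestral / NA
    site_class <- matrix(NA_character_, nrow = nrow(cons),
                         ncol = length(info))
    for (k in seq_len(nrow(cons))) {
      prof <- .consensus_profile(cons$consensus[k], reference,
                                 row$mt_start, row$mt_end)
      idx <- match(info, pos)
      b <- prof[idx]
      h <- vapply(info, function(p) substr(human, p, p), character(1))
      a <- vapply(info, function(p) substr(chimp_mt, p, p), character(1))
      site_class[k, ] <- ifelse(is.na(b), NA,
                                ifelse(b == h, "human",
                                       ifelse(b == a, "ancestral", NA)))
    }
    n_h <- 0L; n_acc <- 0L
    for (j in seq_along(info)) {
      tabj <- table(site_class[, j])
      if (length(tabj) == 0) next
      top <- names(tabj)[which.max(tabj)]
      if (tabj[top] <= nrow(cons) / 2) next     # need majority agreement
      n_acc <- n_acc + 1L
      if (top == "human") n_h <- n_h + 1L
    }
    if (n_acc == 0) next
    r <- n_h / n_acc
    out <- rbind(out, data.frame(
      cohort_numt_id = nid, n_informative = n_acc, n_match_human = n_h,
      r = r, age_myr = (1 - r) * t_div, n_carriers_used = nrow(cons)))
  }
  if (is.null(out))
    out <- data.frame(cohort_numt_id = character(0),
                      n_informative = integer(0), n_match_human = integer(0),
                      r = numeric(0), age_myr = numeric(0),
                      n_carriers_used = integer(0))
  out
}
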