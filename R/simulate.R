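# Synthetic cohort generator.
#
# Donor haplotypes are nuclear reference sequences with mtDNA-derived inserts
# spliced in. Every donor keeps an explicit block map from donor coordinates
# back to reference coordinates, so simulated reads are "aligned" exactly by
# construction: a read inside one block is a plain alignment, a read crossing
# a block boundary becomes a soft-clipped alignment clipped at the junction,
# and mates anchored on opposite sides of a junction become nuclear-mt
# discordant pairs. Junction ambiguity (microhomology) is controlled by
# editing the nuclear flank at construction time so that the realized
# homology equals the declared junction spec exactly.

.with_seed <- function(seed, code) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort simulation design
#'
#' Describes the cohort to simulate: sample roster, trio and tumour-normal
#' structure, sequencing parameters and the master seed. Defaults emulate a
#' standard 30x paired-end short-read cohort (150 bp reads, 400 +/- 50 bp
#' fragments).
#'
#' @param n_samples number of samples (unrelated singletons unless listed in
#'   `trios`/`tumour_pairs`).
#' @param trios list of 3-vectors `c(child, father, mother)` of sample ids.
#' @param tumour_pairs list of 2-vectors `c(tumour, normal)`.
#' @param read_length read length in bp.
#' @param mean_depth mean haploid coverage.
#' @param insert_mean,insert_sd fragment-length distribution (bp).
#' @param seed master seed; the simulation is a pure function of
#'   (design, seed).
#' @param sample_ids optional explicit ids (default `S0001`...).
#' @param decoys optional `interval_track` of nuclear decoy-repeat regions;
#'   alignments falling inside are emitted with MAPQ 0.
#' @param error_rate per-base substitution error rate (default 0: detection
#'   thresholds are count-based, error modelling is orthogonal).
#' @return a `cohort_design`.
#' @export
cohort_design <- function(n_samples, trios = list(), tumour_pairs = list(),
                          read_length = 150L, mean_depth = 30,
                          insert_mean = 400, insert_sd = 50, seed = 1L,
                          sample_ids = NULL, decoys = NULL, error_rate = 0) {
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%04d", seq_len(n_samples))
  if (length(sample_ids) != n_samples) stop("sample_ids length mismatch")
  for (t in trios) {
    if (length(t) != 3 || anyDuplicated(t))
      stop("each trio must be three distinct sample ids")
    if (!all(t %in% sample_ids)) stop("trio member not in sample roster")
  }
  for (p in tumour_pairs) {
    if (length(p) != 2 || anyDuplicated(p))
      stop("each tumour pair must be two distinct sample ids")
    if (!all(p %in% sample_ids)) stop("pair member not in sample roster")
  }
  if (mean_depth < 0) stop("depth must be >= 0")
  structure(list(n_samples = n_samples, sample_ids = sample_ids,
                 trios = trios, tumour_pairs = tumour_pairs,
                 read_length = as.integer(read_length),
                 mean_depth = mean_depth, insert_mean = insert_mean,
                 insert_sd = insert_sd, seed = as.integer(seed),
                 decoys = decoys, error_rate = error_rate),
            class = "cohort_design")
}

#' Family/pair manifest for a design
#'
#' Trio members share a family id; singleton samples are their own family.
#'
#' @param design a `cohort_design`.
#' @return data.frame with `sample`, `role` (child/father/mother/
#'   tumour/normal/singleton), `family`, `pair`.
#' @export
design_manifest <- function(design) {
  m <- data.frame(sample = design$sample_ids, role = "singleton",
                  family = design$sample_ids, pair = NA_character_)
  for (i in seq_along(design$trios)) {
    t <- design$trios[[i]]
    fam <- sprintf("F%04d", i)
    m$role[m$sample %in% t] <- c("child", "father", "mother")[
      match(m$sample[m$sample %in% t], t)]
    m$family[m$sample %in% t] <- fam
  }
  for (i in seq_along(design$tumour_pairs)) {
    p <- design$tumour_pairs[[i]]
    pid <- sprintf("P%04d", i)
    m$role[m$sample == p[1]] <- "tumour"
    m$role[m$sample == p[2]] <- "normal"
    m$pair[m$sample %in% p] <- pid
  }
  m
}

#' Build toy reference genomes
#'
#' Random-base nuclear contigs plus a mitochondrial contig, deterministic for
#' a seed. The mt contig is either the packaged synthetic mitochondrial
#' genome stand-in (`mt_mode = "fixed"`, length 16,569) or a random sequence
#' of `mt_length`.
#'
#' @param nuclear_sizes named integer vector of nuclear contig lengths.
#' @param mt_length mt genome length (used in `"random"` mode).
#' @param seed RNG seed.
#' @param mt_mode `"fixed"` (packaged stand-in) or `"random"`.
#' @param mt_name mt contig name.
#' @return a `numt_reference`.
#' @export
build_toy_references <- function(nuclear_sizes, mt_length = 16569L, seed = 1L,
                                 mt_mode = c("fixed", "random"),
                                 mt_name = "MT") {
  mt_mode <- match.arg(mt_mode)
  if (length(nuclear_sizes) == 0)
    stop("configuration error: need at least one nuclear contig")
  if (is.null(names(nuclear_sizes)))
    names(nuclear_sizes) <- sprintf("chr%d", seq_along(nuclear_sizes))
  if (mt_mode == "fixed" && mt_length != 16569L)
    stop("configuration error: fixed mt mode implies mt_length 16,569")
  if (mt_length < 1000L)
    stop("configuration error: mt_length < 1,000 bp")
  .with_seed(seed, {
    contigs <- vapply(nuclear_sizes, function(n)
      paste(sample(BASES, n, replace = TRUE), collapse = ""), character(1))
    mt <- if (mt_mode == "fixed") synthetic_mt_genome()
          else paste(sample(BASES, mt_length, replace = TRUE), collapse = "")
    reference_genome(c(contigs, setNames(mt, mt_name)), mt_name = mt_name)
  })
}

#' Declare a NUMT to plant
#'
#' @param numt_id identifier.
#' @param nuclear_contig,nuclear_pos insertion point: the insert is spliced
#'   after reference base `nuclear_pos` (1-based).
#' @param segments data.frame with `mt_start`, `mt_end` (1-based inclusive,
#'   `mt_end < mt_start` wraps the origin) and `orientation` (`"+"`/`"-"`);
#'   more than one row makes a concatenated NUMT.
#' @param carriers sample ids carrying the insertion.
#' @param mh_len junction microhomology length (bp, at the 5' junction).
#' @param inserted_bases non-templated bases at the 5' junction; mutually
#'   exclusive with `mh_len > 0`.
#' @param planted_variants optional data.frame `mt_pos`, `alt` and
#'   optionally `carriers` (semicolon-joined sample ids; default all
#'   carriers) of post-insertion substitutions carried by the insert.
#' @param age_fraction expected fraction of human-chimp informative sites in
#'   the fragment carrying the ancestral (chimp) allele; equals
#'   age / T_div under the molecular clock used by the age estimator.
#' @param is_de_novo,is_tumour_specific truth flags carried through to the
#'   truth set.
#' @return a `simulated_numt`.
#' @export
simulated_numt <- function(numt_id, nuclear_contig, nuclear_pos, segments,
                           carriers, mh_len = 0L, inserted_bases = "",
                           planted_variants = NULL, age_fraction = 0,
                           is_de_novo = FALSE, is_tumour_specific = FALSE) {
  if (nrow(segments) < 1) stop("segments must be non-empty")
  if (is.null(segments$orientation)) segments$orientation <- "+"
  if (mh_len > 0 && nzchar(inserted_bases))
    stop("microhomology and inserted bases are mutually exclusive")
  if (age_fraction < 0 || age_fraction > 1) stop("age_fraction in [0,1]")
  structure(list(numt_id = numt_id, nuclear_contig = nuclear_contig,
                 nuclear_pos = as.integer(nuclear_pos), segments = segments,
                 carriers = carriers, mh_len = as.integer(mh_len),
                 inserted_bases = toupper(inserted_bases),
                 planted_variants = planted_variants,
                 age_fraction = age_fraction, is_de_novo = is_de_novo,
                 is_tumour_specific = is_tumour_specific),
            class = "simulated_numt")
}

# Segment length, circular-aware (1-based inclusive ends).
.segment_length <- function(mt_start, mt_end, mt_length) {
  ifelse(mt_end >= mt_start, mt_end - mt_start + 1L,
         mt_length - mt_start + 1L + mt_end)
}

#' Total mtDNA fragment size of a simulated NUMT
#' @param numt a `simulated_numt`.
#' @param mt_length mt genome length.
#' @return size in bp.
#' @export
numt_size <- function(numt, mt_length) {
  sum(.segment_length(numt$segments$mt_start, numt$segments$mt_end, mt_length))
}

# Build the insert sequence and its reference block map for one NUMT.
# Returns list(seq, blocks) where blocks has q_start/q_end (0-based half-open
# offsets within the full insert, i.e. before junction-spec trimming),
# r_start/r_end (0-based half-open on mt) and strand.
.build_insert <- function(ref, numt, chimp_mt = NULL) {
  mt_len <- ref$mt_length
  pieces <- character(0)
  blocks <- NULL
  off <- 0L
  for (i in seq_len(nrow(numt$segments))) {
    s <- numt$segments$mt_start[i]; e <- numt$segments$mt_end[i]
    ori <- numt$segments$orientation[i]
    ni <- normalize_mt_interval(s, e, mt_len)
    segs <- ni$segments            # linear 1-based inclusive parts, in order
    seq_fwd <- paste(substring(ref$contigs[[ref$mt_name]],
                               segs$start, segs$end), collapse = "")
    part_blocks <- data.frame(r_start = segs$start - 1L, r_end = segs$end,
                              strand = "+")
    if (ori == "-") {
      seq_fwd <- revcomp(seq_fwd)
      part_blocks <- part_blocks[rev(seq_len(nrow(part_blocks))), ,
                                 drop = FALSE]
      part_blocks$strand <- "-"
    }
    lens <- part_blocks$r_end - part_blocks$r_start
    part_blocks$q_start <- off + cumsum(c(0L, head(lens, -1)))
    part_blocks$q_end <- part_blocks$q_start + lens
    off <- off + sum(lens)
    pieces <- c(pieces, seq_fwd)
    blocks <- rbind(blocks, part_blocks)
  }
  ins <- paste(pieces, collapse = "")
  chars <- strsplit(ins, "")[[1]]

  # age-dependent reversion to the ancestral allele (shared by all carriers:
  # these differences predate the insertion). The reversion pattern is a
  # deterministic function of the NUMT declaration so that junction
  # validation and planting see the same insert.
  if (numt$age_fraction > 0 && !is.null(chimp_mt)) {
    rev_seed <- (sum(utf8ToInt(numt$numt_id)) * 7919L +
                   numt$segments$mt_start[1] * 13L +
                   as.integer(numt$age_fraction * 1e6)) %% .Machine$integer.max
    info <- informative_sites(ref$contigs[[ref$mt_name]], chimp_mt)
    .with_seed(rev_seed, {
      for (pos in info) {
        m <- .map_mt_pos(blocks, pos)
        if (length(m$q) == 0) next
        if (runif(1) < numt$age_fraction) {
          anc <- substr(chimp_mt, pos, pos)
          for (j in seq_along(m$q)) {
            chars[m$q[j]] <- if (m$strand[j] == "+") anc else revcomp(anc)
          }
        }
      }
      chars
    })
  }
  list(seq = paste(chars, collapse = ""), blocks = blocks)
}

# map an mt position (1-based) to insert offsets (1-based, possibly several
# for repeated segments) together with block strand
.map_mt_pos <- function(blocks, mt_pos) {
  hits <- which(blocks$r_start < mt_pos & blocks$r_end >= mt_pos)
  out <- integer(0); strands <- character(0)
  for (b in hits) {
    if (blocks$strand[b] == "+")
      q <- blocks$q_start[b] + (mt_pos - 1L - blocks$r_start[b]) + 1L
    else
      q <- blocks$q_start[b] + (blocks$r_end[b] - mt_pos) + 1L
    out <- c(out, q); strands <- c(strands, blocks$strand[b])
  }
  list(q = out, strand = strands)
}

# apply planted variants (optionally restricted to one carrier) to an
# insert sequence
.apply_insert_variants <- function(seq, blocks, variants, sample_id) {
  if (is.null(variants) || nrow(variants) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(nrow(variants))) {
    if (!is.null(variants$carriers) && !is.na(variants$carriers[i]) &&
        nzchar(variants$carriers[i])) {
      who <- strsplit(variants$carriers[i], ";")[[1]]
      if (!sample_id %in% who) next
    }
    m <- .map_mt_pos(blocks, variants$mt_pos[i])
    if (length(m$q) == 0)
      stop("planted variant at mt position ", variants$mt_pos[i],
           " outside fragment")
    alt <- toupper(variants$alt[i])
    for (j in seq_along(m$q))
      chars[m$q[j]] <- if (m$strand[j] == "+") alt else revcomp(alt)
  }
  paste(chars, collapse = "")
}

# Reference bases just outside the insert in insert orientation (3 going
# outward on each side), used to break spurious alignment extension across
# junctions. prev[t] faces nuclear position p-..., nxt[t] faces p+t.
.insert_outer_context <- function(ref, numt, depth = 3L) {
  mt <- ref$contigs[[ref$mt_name]]
  L <- ref$mt_length
  wrap <- function(p) ((p - 1L) %% L) + 1L
  base_at <- function(p) substr(mt, wrap(p), wrap(p))
  s1 <- numt$segments$mt_start[1]; o1 <- numt$segments$orientation[1]
  k <- nrow(numt$segments)
  ek <- numt$segments$mt_end[k]; ok <- numt$segments$orientation[k]
  prev <- vapply(seq_len(depth), function(t) {
    if (o1 == "+") base_at(s1 - t)
    else revcomp(base_at(numt$segments$mt_end[1] + t))
  }, character(1))
  nxt <- vapply(seq_len(depth), function(t) {
    if (ok == "+") base_at(ek + t)
    else revcomp(base_at(numt$segments$mt_start[k] - t))
  }, character(1))
  list(prev = prev, nxt = nxt)
}

# Longest overlap (<= cap) between the tail of `left` and the head of
# `right`: max k with substr(left, n-k+1, n) == substr(right, 1, k).
.overlap_scan <- function(left, right, cap = 30L) {
  n <- nchar(left); m <- nchar(right)
  kmax <- min(cap, n, m)
  best <- 0L
  for (k in seq_len(kmax)) {
    if (substr(left, n - k + 1L, n) == substr(right, 1L, k)) best <- k
  }
  best
}

# Compute the nuclear-flank edits that realize the declared junction spec
# exactly (no accidental homology, no alignment extension across junctions).
# Returns a data.frame of single-base edits (contig, pos 1-based, base), or
# signals a condition of class "numt_junction_conflict" when the forced bases
# cannot satisfy all constraints (callers may then resample the fragment).
.junction_edits <- function(ref, numt, insert_full) {
  A <- ref$contigs[[numt$nuclear_contig]]
  p <- numt$nuclear_pos
  m <- numt$mh_len
  s <- numt$inserted_bases
  ctx <- .insert_outer_context(ref, numt)
  Fn <- nchar(insert_full)
  F1 <- substr(insert_full, 1L, 1L)
  Flast <- substr(insert_full, Fn, Fn)
  edits <- NULL
  put <- function(pos, base) rbind(edits, data.frame(contig = numt$nuclear_contig,
                                                     pos = pos, base = base))
  conflict <- function(msg) stop(structure(class = c("numt_junction_conflict",
                                                     "error", "condition"),
                                           list(message = msg, call = NULL)))
  apply_edits <- function(str, ed) {
    if (is.null(ed)) return(str)
    for (i in seq_len(nrow(ed))) substr(str, ed$pos[i], ed$pos[i]) <- ed$base[i]
    str
  }
  fat <- function(i) substr(insert_full, i, i)       # insert base, 1-based
  ftail <- function(t) fat(Fn - t)                   # F[n - t]
  # constrained flank positions with admissible base sets; the admissible
  # sets break contiguous alignment extension across the junctions, and a
  # verification pass rejects assignments with accidental (non-contiguous)
  # homology at either junction
  slots <- list()
  add_slot <- function(pos, excluded) {
    adm <- setdiff(BASES, excluded)
    if (length(adm) == 0) conflict("no admissible flank base")
    slots[[length(slots) + 1L]] <<- list(pos = pos, adm = adm)
  }
  if (m > 0) {
    if (m >= Fn) conflict("microhomology longer than insert")
    for (j in seq_len(m))                  # forced homology tract
      edits <- put(p - m + j, fat(j))
    if (fat(m) == Flast)
      conflict("forced flank base collides with insert tail")
    add_slot(p - m, ctx$prev[1])
    add_slot(p - m - 1L, ctx$prev[2])
    add_slot(p - m - 2L, ctx$prev[3])
  } else if (nzchar(s)) {
    if (substr(s, nchar(s), nchar(s)) == ctx$prev[1])
      conflict("inserted bases extend into mt flank")
    add_slot(p, c(substr(s, 1L, 1L), Flast))
    add_slot(p - 1L, c(ctx$prev[2], ftail(1)))
    add_slot(p - 2L, c(ctx$prev[3], ftail(2)))
  } else {
    add_slot(p, c(F1, ctx$prev[1], Flast))
    add_slot(p - 1L, c(ctx$prev[2], ftail(1)))
    add_slot(p - 2L, c(ctx$prev[3], ftail(2)))
  }
  cont <- if (nzchar(s)) {
    padded <- paste0(s, substr(insert_full, m + 1L, m + 3L))
    c(substr(padded, 1, 1), substr(padded, 2, 2), substr(padded, 3, 3))
  } else c(fat(m + 1L), fat(m + 2L), fat(m + 3L))
  add_slot(p + 1L, c(cont[1], Flast, ctx$nxt[1]))
  add_slot(p + 2L, c(cont[2], ctx$nxt[2]))
  add_slot(p + 3L, c(cont[3], ctx$nxt[3]))

  head30 <- substr(insert_full, 1L, 30L)
  tail30 <- substr(insert_full, max(1L, Fn - 29L), Fn)
  verify <- function(trial_edits) {
    trial <- apply_edits(A, trial_edits)
    left_ok <- .overlap_scan(substr(trial, max(1L, p - 60L), p),
                             head30) == m
    right_ok <- .overlap_scan(tail30,
                              substr(trial, p + 1L, p + 60L)) == 0L
    left_ok && right_ok
  }
  for (attempt in seq_len(60L)) {
    trial_edits <- edits
    for (sl in slots) {
      b <- if (attempt == 1L) sl$adm[1]
           else sample(sl$adm, 1)
      trial_edits <- rbind(trial_edits,
                           data.frame(contig = numt$nuclear_contig,
                                      pos = sl$pos, base = b))
    }
    if (verify(trial_edits)) return(trial_edits)
  }
  conflict("cannot realize declared junction ambiguity")
}

#' Plant NUMTs into donor haplotypes
#'
#' Produces per-sample donor genomes (nuclear sequences with the
#' mtDNA-derived inserts of the NUMTs each sample carries) plus a
#' machine-readable truth table. Junction specs are realized exactly: the
#' nuclear flank around each insertion point is edited so the observable
#' microhomology/insertion structure equals the declaration (shared bases
#' appear once in the donor; inserted bases align to neither reference).
#'
#' @param reference a `numt_reference` (returned adjusted: flank edits are
#'   part of the reference all downstream steps use).
#' @param numts list of `simulated_numt`.
#' @param design a `cohort_design`.
#' @param chimp_mt optional ancestral mt sequence for age-dependent
#'   divergence (default the packaged synthetic ancestral stand-in).
#' @return list with `reference` (edited), `donors` (per sample: per contig
#'   `seq` + `blocks` map), `truth` (data.frame, one row per NUMT x carrier)
#'   and `design`.
#' @export
plant_numts <- function(reference, numts, design,
                        chimp_mt = synthetic_chimp_mt()) {
  rl <- design$read_length
  for (nu in numts) {
    if (!nu$nuclear_contig %in% names(reference$contigs))
      stop("unknown nuclear contig: ", nu$nuclear_contig)
    L <- nchar(reference$contigs[[nu$nuclear_contig]])
    if (nu$nuclear_pos < rl || nu$nuclear_pos > L - rl)
      stop("insertion point within a read length of contig end")
    if (any(.segment_length(nu$segments$mt_start, nu$segments$mt_end,
                            reference$mt_length) < 24))
      stop("segment shorter than 24 bp (smallest observed NUMT)")
    if (!all(nu$carriers %in% design$sample_ids))
      stop("carrier not in sample roster")
  }
  # overlapping insertions on one haplotype are a design error
  for (sid in design$sample_ids) {
    mine <- Filter(function(n) sid %in% n$carriers, numts)
    if (length(mine) < 2) next
    tab <- data.frame(contig = vapply(mine, `[[`, "", "nuclear_contig"),
                      pos = vapply(mine, function(n) n$nuclear_pos, 0L))
    for (ctg in unique(tab$contig)) {
      pp <- sort(tab$pos[tab$contig == ctg])
      if (length(pp) > 1 && min(diff(pp)) < 200)
        stop("design error: overlapping planted NUMTs on one haplotype")
    }
  }

  .with_seed(design$seed, {
    inserts <- lapply(numts, function(nu) .build_insert(reference, nu, chimp_mt))
    # apply junction flank edits to the shared reference
    for (i in seq_along(numts)) {
      ed <- .junction_edits(reference, numts[[i]], inserts[[i]]$seq)
      if (!is.null(ed)) {
        for (j in seq_len(nrow(ed))) {
          ctg <- ed$contig[j]
          substr(reference$contigs[[ctg]], ed$pos[j], ed$pos[j]) <- ed$base[j]
        }
      }
    }
    # rebuild inserts against the edited reference (mt untouched, but keep
    # the invariant obvious), then splice donors
    donors <- list()
    for (sid in design$sample_ids) {
      donor <- list()
      for (ctg in setdiff(names(reference$contigs), reference$mt_name)) {
        idx <- which(vapply(numts, function(n)
          n$nuclear_contig == ctg && sid %in% n$carriers, logical(1)))
        A <- reference$contigs[[ctg]]
        LA <- nchar(A)
        if (length(idx) == 0) {
          donor[[ctg]] <- list(
            seq = A,
            blocks = data.frame(d_start = 0L, d_end = LA, contig = ctg,
                                r_start = 0L, r_end = LA, strand = "+"))
          next
        }
        idx <- idx[order(vapply(numts[idx], function(n) n$nuclear_pos, 0L))]
        pieces <- character(0)
        blocks <- NULL
        cur_ref <- 0L   # 0-based ref offset consumed
        cur_d <- 0L     # donor length so far
        for (i in idx) {
          nu <- numts[[i]]
          ins <- inserts[[i]]
          p <- nu$nuclear_pos
          trim <- nu$mh_len                 # shared bases appear once
          extra <- nu$inserted_bases
          nuc_piece <- substr(A, cur_ref + 1L, p)
          pieces <- c(pieces, nuc_piece)
          blocks <- rbind(blocks, data.frame(
            d_start = cur_d, d_end = cur_d + nchar(nuc_piece), contig = ctg,
            r_start = cur_ref, r_end = p, strand = "+"))
          cur_d <- cur_d + nchar(nuc_piece)
          cur_ref <- p
          if (nzchar(extra)) {              # junction-only bases: no block
            pieces <- c(pieces, extra)
            cur_d <- cur_d + nchar(extra)
          }
          ins_seq_s <- .apply_insert_variants(ins$seq, ins$blocks,
                                              nu$planted_variants, sid)
          body <- substr(ins_seq_s, trim + 1L, nchar(ins_seq_s))
          pieces <- c(pieces, body)
          ib <- ins$blocks
          for (b in seq_len(nrow(ib))) {
            qs <- ib$q_start[b]; qe <- ib$q_end[b]
            # trim the first `trim` query bases off the block map
            nqs <- max(qs, trim); nqe <- qe
            if (nqs >= nqe) next
            rs <- ib$r_start[b]; re <- ib$r_end[b]
            if (ib$strand[b] == "+") rs <- rs + (nqs - qs)
            else re <- re - (nqs - qs)
            blocks <- rbind(blocks, data.frame(
              d_start = cur_d + (nqs - trim), d_end = cur_d + (nqe - trim),
              contig = reference$mt_name, r_start = rs, r_end = re,
              strand = ib$strand[b]))
          }
          cur_d <- cur_d + nchar(body)
        }
        tail_piece <- substr(A, cur_ref + 1L, LA)
        pieces <- c(pieces, tail_piece)
        blocks <- rbind(blocks, data.frame(
          d_start = cur_d, d_end = cur_d + nchar(tail_piece), contig = ctg,
          r_start = cur_ref, r_end = LA, strand = "+"))
        donor[[ctg]] <- list(seq = paste(pieces, collapse = ""),
                             blocks = blocks)
      }
      donors[[sid]] <- donor
    }

    truth <- do.call(rbind, lapply(numts, function(nu) {
      seg_str <- paste(sprintf("%d-%d:%s", nu$segments$mt_start,
                               nu$segments$mt_end, nu$segments$orientation),
                       collapse = ";")
      var_str <- vapply(nu$carriers, function(sid) {
        pv <- nu$planted_variants
        if (is.null(pv) || nrow(pv) == 0) return("")
        mine <- vapply(seq_len(nrow(pv)), function(i) {
          cc <- if (is.null(pv$carriers)) NA else pv$carriers[i]
          is.na(cc) || !nzchar(cc) || sid %in% strsplit(cc, ";")[[1]]
        }, logical(1))
        paste(sprintf("%d>%s", pv$mt_pos[mine], pv$alt[mine]),
              collapse = ";")
      }, character(1))
      data.frame(numt_id = nu$numt_id, sample_id = nu$carriers,
                 nuclear_contig = nu$nuclear_contig,
                 nuclear_pos = nu$nuclear_pos, segments = seg_str,
                 n_segments = nrow(nu$segments),
                 size_bp = numt_size(nu, reference$mt_length),
                 mt_start = nu$segments$mt_start[1],
                 mt_end = nu$segments$mt_end[nrow(nu$segments)],
                 mh_len = nu$mh_len, inserted_bases = nu$inserted_bases,
                 variants = var_str, age_fraction = nu$age_fraction,
                 is_de_novo = nu$is_de_novo,
                 is_tumour_specific = nu$is_tumour_specific)
    }))
    rownames(truth) <- NULL
    list(reference = reference, donors = donors, truth = truth,
         design = design)
  })
}

# Map one donor-read interval [a, b) (+ strand of sequencing) to an
# alignment against the reference using the donor block map.
.map_read <- function(blocks, a, b, donor_seq, mate2) {
  hit <- which(blocks$d_start < b & blocks$d_end > a)
  frag <- substr(donor_seq, a + 1L, b)
  if (length(hit) == 0) {        # read entirely in junction-only bases
    return(list(contig = NA_character_, start = NA_integer_, cigar = "*",
                reverse = mate2, seq = frag, mapq = 0L))
  }
  ov <- pmin(blocks$d_end[hit], b) - pmax(blocks$d_start[hit], a)
  k <- hit[which.max(ov)]
  qa <- max(blocks$d_start[k], a); qb <- min(blocks$d_end[k], b)
  left <- qa - a; right <- b - qb; mid <- qb - qa
  if (blocks$strand[k] == "+") {
    rstart <- blocks$r_start[k] + (qa - blocks$d_start[k])
    cig <- paste0(if (left > 0) paste0(left, "S") else "", mid, "M",
                  if (right > 0) paste0(right, "S") else "")
    seq_out <- frag
    rev <- mate2
  } else {
    rstart <- blocks$r_start[k] + (blocks$d_end[k] - qb)
    cig <- paste0(if (right > 0) paste0(right, "S") else "", mid, "M",
                  if (left > 0) paste0(left, "S") else "")
    seq_out <- revcomp(frag)
    rev <- !mate2
  }
  list(contig = blocks$contig[k], start = rstart, cigar = cig,
       reverse = rev, seq = seq_out, mapq = 60L)
}

#' Simulate cohort paired-end reads
#'
#' Uniform read placement at the design depth over each donor haplotype;
#' fragment lengths Normal(insert_mean, insert_sd) truncated at the read
#' length. Reads overlapping an insertion junction are emitted as
#' soft-clipped alignments clipped at the junction; mates anchored on
#' opposite sides become nuclear-mt discordant pairs. MAPQ is 60 except
#' inside configured decoy regions (0). Deterministic per design seed.
#'
#' @param planted result of [plant_numts()].
#' @return named list (per sample) of alignment data.frames in the
#'   [read_alignments()] column layout.
#' @export
simulate_cohort_reads <- function(planted) {
  design <- planted$design
  ref <- planted$reference
  rl <- design$read_length
  if (design$mean_depth < 0) stop("configuration error: depth < 0")
  decoy_iv <- if (!is.null(design$decoys)) design$decoys$intervals else NULL
  out <- list()
  .with_seed(design$seed + 1L, {
    for (sid in design$sample_ids) {
      recs <- list()
      donor <- planted$donors[[sid]]
      for (ctg in names(donor)) {
        dseq <- donor[[ctg]]$seq
        blocks <- donor[[ctg]]$blocks
        L <- nchar(dseq)
        n_pairs <- round(design$mean_depth * L / (2 * rl))
        if (n_pairs <= 0) next
        frag <- pmin(pmax(round(rnorm(n_pairs, design$insert_mean,
                                      design$insert_sd)), rl), L)
        f <- floor(runif(n_pairs, 0, L - frag + 1))
        ids <- sprintf("%s_%s_%06d", sid, ctg, seq_len(n_pairs))

        map_ends <- function(a, b, mate2) {
          n <- length(a)
          contig <- character(n); start <- integer(n); cig <- character(n)
          rev <- logical(n); sq <- character(n); mapq <- integer(n)
          # fast path: read fully inside one plus-strand block
          k <- findInterval(a, blocks$d_start)
          fast <- k >= 1 & b <= blocks$d_end[pmax(k, 1L)] &
            a >= blocks$d_start[pmax(k, 1L)] & blocks$strand[pmax(k, 1L)] == "+"
          kf <- k[fast]
          contig[fast] <- blocks$contig[kf]
          start[fast] <- blocks$r_start[kf] + (a[fast] - blocks$d_start[kf])
          cig[fast] <- paste0(b[fast] - a[fast], "M")
          rev[fast] <- mate2
          sq[fast] <- substring(dseq, a[fast] + 1L, b[fast])
          mapq[fast] <- 60L
          for (i in which(!fast)) {
            r <- .map_read(blocks, a[i], b[i], dseq, mate2 = mate2)
            contig[i] <- r$contig; start[i] <- r$start; cig[i] <- r$cigar
            rev[i] <- r$reverse; sq[i] <- r$seq; mapq[i] <- r$mapq
          }
          list(contig = contig, start = start, cigar = cig, reverse = rev,
               seq = sq, mapq = mapq)
        }
        m1 <- map_ends(f, f + rl, mate2 = FALSE)
        m2 <- map_ends(f + frag - rl, f + frag, mate2 = TRUE)
        mk <- function(r, mate_r, is_first) {
          flag <- SAM_FLAG$paired +
            (if (is_first) SAM_FLAG$first else SAM_FLAG$last) +
            ifelse(r$reverse, SAM_FLAG$reverse, 0L) +
            ifelse(!is.na(mate_r$contig) & mate_r$reverse,
                   SAM_FLAG$mate_reverse, 0L) +
            ifelse(is.na(r$contig), SAM_FLAG$unmapped, 0L) +
            ifelse(is.na(mate_r$contig), SAM_FLAG$mate_unmapped, 0L)
          data.frame(read_id = ids, sample_id = sid, flag = flag,
                     contig = r$contig, start = r$start, mapq = r$mapq,
                     cigar = r$cigar, strand = ifelse(r$reverse, "-", "+"),
                     mate_contig = mate_r$contig,
                     mate_start = ifelse(is.na(mate_r$start), 0L,
                                         mate_r$start),
                     seq = r$seq, is_first = is_first,
                     is_supplementary = FALSE)
        }
        recs[[ctg]] <- rbind(mk(m1, m2, TRUE), mk(m2, m1, FALSE))
      }
      reads <- if (length(recs)) do.call(rbind, recs) else
        read_alignments_empty()
      rownames(reads) <- NULL
      # decoy repeats: MAPQ 0
      if (!is.null(decoy_iv) && nrow(reads) > 0) {
        for (j in seq_len(nrow(decoy_iv))) {
          hit <- !is.na(reads$contig) & reads$contig == decoy_iv$contig[j] &
            reads$start < decoy_iv$end[j] &
            (reads$start + vapply(reads$cigar, cigar_reference_length, 0L)) >
              decoy_iv$start[j]
          reads$mapq[hit] <- 0L
        }
      }
      # optional uniform substitution errors
      if (design$error_rate > 0 && nrow(reads) > 0) {
        for (i in seq_len(nrow(reads))) {
          s <- strsplit(reads$seq[i], "")[[1]]
          hit <- which(runif(length(s)) < design$error_rate)
          if (length(hit)) {
            s[hit] <- vapply(s[hit], function(b)
              sample(setdiff(BASES, b), 1), character(1))
            reads$seq[i] <- paste(s, collapse = "")
          }
        }
      }
      out[[sid]] <- reads
    }
  })
  out
}

# empty alignment frame with the canonical columns
read_alignments_empty <- function() {
  data.frame(read_id = character(0), sample_id = character(0),
             flag = integer(0), contig = character(0), start = integer(0),
             mapq = integer(0), cigar = character(0), strand = character(0),
             mate_contig = character(0), mate_start = integer(0),
             seq = character(0), is_first = logical(0),
             is_supplementary = logical(0))
}

#' Write simulated cohort to disk
#'
#' @param planted result of [plant_numts()].
#' @param reads result of [simulate_cohort_reads()].
#' @param dir output directory; writes `reference.fa`, one SAM per sample,
#'   `truth.json` and `manifest.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(planted, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(planted$reference, file.path(dir, "reference.fa"))
  for (sid in names(reads))
    write_sam(reads[[sid]], planted$reference,
              file.path(dir, paste0(sid, ".sam")))
  write_truth_set(planted$truth, planted$design, file.path(dir, "truth.json"))
  write.table(design_manifest(planted$design),
              file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Write the truth set as JSON
#' @param truth truth data.frame from [plant_numts()].
#' @param design the `cohort_design` (seed and parameters are recorded).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_set <- function(truth, design, path) {
  obj <- list(
    parameters = list(n_samples = design$n_samples, seed = design$seed,
                      read_length = design$read_length,
                      mean_depth = design$mean_depth,
                      insert_mean = design$insert_mean,
                      insert_sd = design$insert_sd),
    records = truth
  )
  ok <- tryCatch({
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stop("cannot write truth set to ", path)
  invisible(path)
}

#' Read a truth set back
#' @param path JSON written by [write_truth_set()].
#' @return list with `parameters` and `records` (data.frame).
#' @export
read_truth_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$records <- as.data.frame(obj$records)
  obj
}

#' Sample random NUMTs with clean junctions
#'
#' Draws NUMT declarations (position, fragment, junction class) whose
#' junction specs are realizable exactly against the given reference;
#' fragments whose forced flank bases would create accidental homology are
#' re-drawn. Class mixture defaults reflect the germline junction-mechanism
#' proportions this pipeline is designed to measure (about half
#' microhomology, a quarter blunt, a fifth insertion).
#'
#' @param reference a `numt_reference`.
#' @param design a `cohort_design` (read length bounds insertion points).
#' @param n number of NUMTs.
#' @param size_range mt fragment size range in bp.
#' @param carriers_list list of carrier id vectors, one per NUMT.
#' @param class_probs probabilities for (microhomology, blunt, insertion).
#' @param mh_range,ins_range microhomology / inserted-bases length ranges.
#' @param age_fraction scalar or vector of ancestral-allele fractions.
#' @param min_gap minimum spacing between insertion points on a contig.
#' @param seed RNG seed.
#' @param chimp_mt ancestral mt sequence used when `age_fraction > 0`
#'   (junction viability is checked on the reverted insert); defaults to
#'   the synthetic ancestral stand-in derived from the reference mt.
#' @return list of `simulated_numt`.
#' @export
sample_numts <- function(reference, design, n, size_range = c(100, 2000),
                         carriers_list, class_probs = c(0.519, 0.276, 0.205),
                         mh_range = c(1, 8), ins_range = c(1, 6),
                         age_fraction = 0, min_gap = 2000L, seed = 1L,
                         chimp_mt = NULL) {
  stopifnot(length(carriers_list) == n)
  if (length(age_fraction) == 1) age_fraction <- rep(age_fraction, n)
  if (is.null(chimp_mt) && any(age_fraction > 0))
    chimp_mt <- synthetic_chimp_mt(reference$contigs[[reference$mt_name]])
  nuclear <- setdiff(names(reference$contigs), reference$mt_name)
  .with_seed(seed, {
    used <- list()
    out <- vector("list", n)
    for (i in seq_len(n)) {
      for (attempt in seq_len(200)) {
        ctg <- sample(nuclear, 1)
        L <- nchar(reference$contigs[[ctg]])
        pos <- sample(seq(design$read_length + 50L, L - design$read_length - 50L), 1)
        prior <- used[[ctg]]
        if (!is.null(prior) && any(abs(prior - pos) < min_gap)) next
        size <- sample(seq(size_range[1], size_range[2]), 1)
        s <- sample(seq_len(reference$mt_length), 1)
        e <- ((s + size - 2L) %% reference$mt_length) + 1L
        cls <- sample(c("mh", "blunt", "ins"), 1, prob = class_probs)
        mh <- if (cls == "mh") sample(seq(mh_range[1], mh_range[2]), 1) else 0L
        ins <- if (cls == "ins")
          paste(sample(BASES, sample(seq(ins_range[1], ins_range[2]), 1),
                       replace = TRUE), collapse = "") else ""
        nu <- simulated_numt(sprintf("numt%03d", i), ctg, pos,
                             data.frame(mt_start = s, mt_end = e,
                                        orientation = "+"),
                             carriers = carriers_list[[i]], mh_len = mh,
                             inserted_bases = ins,
                             age_fraction = age_fraction[i])
        check <- tryCatch({
          insert <- .build_insert(reference, nu, chimp_mt = chimp_mt)
          .junction_edits(reference, nu, insert$seq)
          TRUE
        }, numt_junction_conflict = function(e) FALSE)
        if (isTRUE(check)) {
          used[[ctg]] <- c(prior, pos)
          out[[i]] <- nu
          break
        }
      }
      if (is.null(out[[i]]))
        stop("could not place NUMT ", i, " with a clean junction")
    }
    out
  })
}
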