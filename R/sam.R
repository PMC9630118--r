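# Minimal SAM reader/writer for the pipeline's needs: the 11 mandatory
# fields, flags 0x1/0x10/0x40/0x80/0x100/0x4/0x800, soft/hard clips preserved.
# Record order in the file is preserved on read (a contract the detection and
# simulation round-trip tests rely on). Full SAM compliance is a non-goal.

SAM_FLAG <- list(paired = 1L, unmapped = 4L, mate_unmapped = 8L,
                 reverse = 16L, mate_reverse = 32L, first = 64L,
                 last = 128L, secondary = 256L, supplementary = 2048L)

.has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Parse a CIGAR string
#' @param cigar CIGAR string (e.g. `"30S120M"`), or `"*"`.
#' @return data.frame with columns `op`, `len`; zero rows for `"*"`.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*")
    return(data.frame(op = character(0), len = integer(0)))
  ops <- gsub("[0-9]+", "", cigar)
  if (!grepl("^([0-9]+[MIDSH])+$", cigar))
    stop("unsupported CIGAR: ", cigar)
  data.frame(
    op = strsplit(ops, "")[[1]],
    len = as.integer(strsplit(gsub("[MIDSH]", ",", cigar), ",")[[1]])
  )
}

#' Query bases consumed by a CIGAR
#' @param cigar CIGAR string.
#' @return number of read bases covered by M/I/S operations.
#' @export
cigar_query_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I", "S")])
}

#' Reference bases consumed by a CIGAR
#' @param cigar CIGAR string.
#' @return number of reference bases covered by M/D operations.
#' @export
cigar_reference_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D")])
}

#' Soft-clip lengths at either end of a CIGAR
#' @param cigar CIGAR string.
#' @return named integer vector `c(left =, right =)`.
#' @export
cigar_clips <- function(cigar) {
  cg <- parse_cigar(cigar)
  left <- if (nrow(cg) > 0 && cg$op[1] == "S") cg$len[1] else 0L
  right <- if (nrow(cg) > 0 && cg$op[nrow(cg)] == "S") cg$len[nrow(cg)] else 0L
  c(left = left, right = right)
}

# vectorized soft-clip lengths for a cigar vector (hot path)
.clips_vec <- function(cigars) {
  left <- rep(0L, length(cigars))
  right <- rep(0L, length(cigars))
  has_l <- grepl("^[0-9]+S", cigars)
  left[has_l] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cigars[has_l]))
  has_r <- grepl("[A-Z][0-9]+S$", cigars)
  right[has_r] <- as.integer(sub("^.*[A-Z]([0-9]+)S$", "\\1",
                                 cigars[has_r]))
  cbind(left = left, right = right)
}

#' Read paired-end alignments from a SAM file
#'
#' Parses the 11 mandatory SAM fields into a data.frame of alignments with
#' 0-based start coordinates (SAM POS is 1-based). Soft and hard clips are
#' preserved in the CIGAR. Records are returned in file order; MAPQ-0 reads
#' are retained (filtering happens downstream in detection).
#'
#' @param path SAM file.
#' @param reference a `numt_reference`; header `@SQ` contigs and record
#'   contigs are checked against it.
#' @param sample_id sample label attached to every record (default: file base
#'   name without extension).
#' @return data.frame with columns `read_id`, `sample_id`, `flag`, `contig`
#'   (NA if unmapped), `start` (0-based), `mapq`, `cigar`, `strand`,
#'   `mate_contig`, `mate_start` (0-based), `seq`, `is_first`,
#'   `is_supplementary`.
#' @export
read_alignments <- function(path, reference, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  for (h in sq) {
    fields_h <- strsplit(h, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", grep("^SN:", fields_h, value = TRUE)[1])
    ln_f <- grep("^LN:", fields_h, value = TRUE)
    ln <- if (length(ln_f)) as.integer(sub("^LN:", "", ln_f[1])) else NA
    if (is.na(sn) || !sn %in% names(reference$contigs))
      stop("header contig '", sn, "' absent from reference")
    if (!is.na(ln) && ln != nchar(reference$contigs[[sn]]))
      stop("header length for '", sn, "' disagrees with reference")
  }
  if (length(body) == 0) {
    return(data.frame(read_id = character(0), sample_id = character(0),
                      flag = integer(0), contig = character(0),
                      start = integer(0), mapq = integer(0),
                      cigar = character(0), strand = character(0),
                      mate_contig = character(0), mate_start = integer(0),
                      seq = character(0), is_first = logical(0),
                      is_supplementary = logical(0)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("truncated SAM record at line ",
         which(!startsWith(lines, "@"))[which(nf < 11)[1]])
  g <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(g(2))
  rname <- g(3)
  contig <- ifelse(rname == "*" | .has_flag(flag, SAM_FLAG$unmapped),
                   NA_character_, rname)
  known <- contig[!is.na(contig)]
  if (length(known) && !all(known %in% names(reference$contigs)))
    stop("record contig(s) absent from reference: ",
         paste(unique(setdiff(known, names(reference$contigs))), collapse = ", "))
  mate_rname <- g(7)
  mate_contig <- ifelse(mate_rname == "*", NA_character_,
                        ifelse(mate_rname == "=", contig, mate_rname))
  data.frame(
    read_id = g(1), sample_id = sample_id, flag = flag, contig = contig,
    start = as.integer(g(4)) - 1L, mapq = as.integer(g(5)), cigar = g(6),
    strand = ifelse(.has_flag(flag, SAM_FLAG$reverse), "-", "+"),
    mate_contig = mate_contig, mate_start = as.integer(g(8)) - 1L,
    seq = g(10), is_first = .has_flag(flag, SAM_FLAG$first),
    is_supplementary = .has_flag(flag, SAM_FLAG$supplementary)
  )
}

#' Write alignments to a SAM file
#'
#' Inverse of [read_alignments()] for records produced by this package;
#' coordinates convert back from internal 0-based to SAM 1-based.
#'
#' @param reads alignment data.frame (columns as in [read_alignments()]).
#' @param reference a `numt_reference`, used for the `@SQ` header.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference$contigs),
                   nchar(reference$contigs)))
  if (nrow(reads) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  rname <- ifelse(is.na(reads$contig), "*", reads$contig)
  rnext <- ifelse(is.na(reads$mate_contig), "*",
                  ifelse(!is.na(reads$contig) &
                           reads$mate_contig == reads$contig, "=",
                         reads$mate_contig))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
                  reads$read_id, reads$flag, rname, reads$start + 1L,
                  reads$mapq, reads$cigar, rnext, reads$mate_start + 1L,
                  reads$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an annotation track (BED or deletion-list TSV)
#'
#' BED is parsed 0-based half-open; a mitochondrial deletion list (columns
#' `del5`, `del3`, 1-based breakpoint positions) is converted to the internal
#' 0-based half-open convention with the original breakpoint pair retained.
#'
#' @param path input file.
#' @param kind one of `"bed"`, `"mito_deletions"`, `"known_numts"`
#'   (`known_numts` is BED-dialect).
#' @param mt_name contig name assigned to deletion intervals.
#' @param contig_lengths optional named vector for range checking.
#' @return an `interval_track`: list with `name`, `kind` and `intervals`
#'   (data.frame `contig`, `start`, `end` 0-based half-open, `label`), sorted
#'   within contig.
#' @export
read_intervals <- function(path, kind = c("bed", "mito_deletions", "known_numts"),
                           mt_name = "MT", contig_lengths = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (kind == "mito_deletions") {
    tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("del5", "del3") %in% names(tab)))
      stop("deletion list must have columns del5, del3")
    iv <- data.frame(contig = mt_name, start = tab$del5 - 1L, end = tab$del3,
                     label = sprintf("del_%d_%d", tab$del5, tab$del3))
    iv$del5 <- tab$del5
    iv$del3 <- tab$del3
  } else {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 3) stop("BED needs at least 3 columns")
    iv <- data.frame(contig = as.character(tab[[1]]),
                     start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                     label = if (ncol(tab) >= 4) as.character(tab[[4]])
                             else NA_character_)
  }
  if (any(iv$start >= iv$end))
    stop("interval with start >= end in ", path)
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[iv$contig]
    if (any(!is.na(len) & iv$end > len))
      stop("interval end exceeds contig length in ", path)
  }
  iv <- iv[order(iv$contig, iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  structure(list(name = sub("\\.[^.]*$", "", basename(path)), kind = kind,
                 intervals = iv),
            class = "interval_track")
}

#' Construct an interval track in memory
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `label`.
#' @param name track name.
#' @return an `interval_track`.
#' @export
interval_track <- function(intervals, name = "track") {
  if (!all(c("contig", "start", "end") %in% names(intervals)))
    stop("intervals need columns contig, start, end")
  if (is.null(intervals$label))
    intervals$label <- rep(NA_character_, nrow(intervals))
  if (any(intervals$start >= intervals$end))
    stop("interval with start >= end")
  intervals <- intervals[order(intervals$contig, intervals$start,
                               intervals$end), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(name = name, kind = "bed", intervals = intervals),
            class = "interval_track")
}

#' Write an interval track as BED
#' @param track an `interval_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  iv <- track$intervals
  lab <- ifelse(is.na(iv$label), ".", iv$label)
  writeLines(sprintf("%s\t%d\t%d\t%s", iv$contig, iv$start, iv$end, lab), path)
  invisible(path)
}
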