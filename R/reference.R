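#' @importFrom stats rbinom rnorm runif rpois median sd cor.test wilcox.test
#'   fisher.test qbeta binom.test lm pchisq pnorm pt setNames complete.cases
#' @importFrom utils read.table write.table head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Reference genome container
#'
#' Holds a set of nuclear contigs plus one mitochondrial contig, as uppercase
#' character strings over the alphabet ACGTN. The mitochondrial contig is
#' flagged circular: interval arithmetic on it (see
#' [normalize_mt_interval()], [circular_distance()]) wraps around the origin,
#' while alignments are taken as given on the linearized sequence.
#'
#' @param contigs named character vector of sequences (A/C/G/T/N).
#' @param mt_name name of the mitochondrial contig; must be present in
#'   `contigs`.
#' @param circular logical; whether the mt contig is treated as circular.
#' @return An object of class `numt_reference` with elements `contigs`,
#'   `mt_name`, `mt_length` and `circular`.
#' @export
reference_genome <- function(contigs, mt_name = "MT", circular = TRUE) {
  if (length(contigs) == 0 || is.null(names(contigs)) || any(names(contigs) == ""))
    stop("contigs must be a non-empty named character vector")
  contigs <- vapply(contigs, toupper, character(1))
  if (any(nchar(contigs) == 0))
    stop("all contig sequences must be non-empty")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig(s) contain characters outside ACGTN: ",
         paste(names(contigs)[bad], collapse = ", "))
  if (!mt_name %in% names(contigs))
    stop("mt contig '", mt_name, "' not found among contigs")
  structure(
    list(contigs = contigs, mt_name = mt_name,
         mt_length = nchar(contigs[[mt_name]]), circular = circular),
    class = "numt_reference"
  )
}

#' @export
print.numt_reference <- function(x, ...) {
  cat("numt_reference:", length(x$contigs), "contig(s);",
      "mt =", x$mt_name, sprintf("(%d bp%s)\n", x$mt_length,
                                 if (x$circular) ", circular" else ""))
  invisible(x)
}

#' Contig sequence accessor
#' @param ref a `numt_reference`.
#' @param contig contig name.
#' @return the sequence as a single string.
#' @export
ref_seq <- function(ref, contig) {
  if (!contig %in% names(ref$contigs)) stop("unknown contig: ", contig)
  ref$contigs[[contig]]
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on load. The mitochondrial contig is identified by
#' name among the conventional aliases (default `"chrM"`, `"MT"`).
#'
#' @param path FASTA file.
#' @param mt_names candidate names for the mitochondrial contig; the first one
#'   present is used.
#' @param circular whether to flag the mt contig circular.
#' @return a `numt_reference`.
#' @export
read_fasta <- function(path, mt_names = c("chrM", "MT"), circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0) stop("malformed FASTA: no records in ", path)
  contigs <- setNames(toupper(as.character(seqs)),
                      sub("\\s.*$", "", names(seqs)))
  mt <- mt_names[mt_names %in% names(contigs)]
  if (length(mt) == 0)
    stop("no mitochondrial contig found (looked for: ",
         paste(mt_names, collapse = ", "), ")")
  reference_genome(contigs, mt_name = mt[[1]], circular = circular)
}

#' Write a reference genome to FASTA
#' @param ref a `numt_reference`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$contigs), path)
  invisible(path)
}

#' Reverse complement of a sequence string
#' @param x character vector of DNA strings.
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize a (possibly origin-crossing) mtDNA interval
#'
#' Positions are 1-based inclusive on the circular mitochondrial genome
#' (MitoMap convention). An interval whose end precedes its start crosses the
#' origin and is returned as two linear sub-intervals; the total length is
#' computed modulo the genome length. Idempotent on linear intervals.
#'
#' @param start,end 1-based inclusive positions, both in `[1, mt_length]`.
#' @param mt_length mt genome length in bp.
#' @return a list with `segments` (data.frame of `start`, `end`, linear,
#'   1-based inclusive) and `length` (total bp).
#' @export
normalize_mt_interval <- function(start, end, mt_length) {
  if (mt_length < 1) stop("mt_length must be >= 1")
  if (start < 1 || start > mt_length || end < 1 || end > mt_length)
    stop("positions must lie in [1, ", mt_length, "]")
  if (start != round(start) || end != round(end))
    stop("positions must be integers")
  if (end >= start) {
    segs <- data.frame(start = start, end = end)
  } else {
    segs <- data.frame(start = c(start, 1), end = c(mt_length, end))
  }
  len <- sum(segs$end - segs$start + 1L)
  if (len == 0 || len > mt_length) stop("zero-length mt interval")
  list(segments = segs, length = len)
}

#' Circular distance between two mtDNA positions
#' @param a,b positions (1-based); vectors recycle.
#' @param mt_length genome length.
#' @return minimum of the linear and wrap-around distance.
#' @export
circular_distance <- function(a, b, mt_length) {
  d <- abs(a - b)
  pmin(d, mt_length - d)
}

#' Extract an mtDNA fragment, circular-aware
#'
#' @param ref a `numt_reference`.
#' @param start,end 1-based inclusive mt positions; `end < start` wraps
#'   around the origin.
#' @return fragment sequence string.
#' @export
mt_fragment <- function(ref, start, end) {
  ni <- normalize_mt_interval(start, end, ref$mt_length)
  mt <- ref$contigs[[ref$mt_name]]
  paste(substring(mt, ni$segments$start, ni$segments$end), collapse = "")
}

# Deterministic synthetic sequence generator used by the packaged stand-ins.
# Draws from a private RNG stream so callers' RNG state is untouched.
.synth_seq <- function(n, seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Synthetic human mitochondrial genome (stand-in)
#'
#' A deterministic 16,569 bp random sequence standing in for the human rCRS
#' mitochondrial reference, which is not redistributed with the package. Real
#' data can be supplied via [read_fasta()]. The sequence is a fixed function
#' of an internal seed, so every call returns the same genome.
#'
#' @param length genome length in bp (default 16,569, the rCRS length).
#' @return sequence string.
#' @export
synthetic_mt_genome <- function(length = 16569L) {
  .synth_seq(length, seed = 160569L)
}

#' Synthetic chimpanzee ancestral mitochondrial sequence (stand-in)
#'
#' Derived deterministically from [synthetic_mt_genome()] by substituting a
#' fixed fraction of sites, emulating human-chimpanzee mtDNA divergence
#' (default 8%, a realistic mitochondrial figure). Positions are kept aligned
#' one-to-one with the human sequence (no indels), so site-wise comparison
#' needs no realignment.
#'
#' @param human_mt human mt sequence string (default the packaged stand-in).
#' @param divergence per-site substitution probability.
#' @return sequence string of the same length.
#' @export
synthetic_chimp_mt <- function(human_mt = synthetic_mt_genome(),
                               divergence = 0.08) {
  n <- nchar(human_mt)
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(607300L)
  flip <- which(runif(n) < divergence)
  s <- strsplit(human_mt, "")[[1]]
  s[flip] <- vapply(s[flip], function(b) sample(setdiff(BASES, b), 1),
                    character(1))
  paste(s, collapse = "")
}

#' Informative (human-ancestral differing) mtDNA sites
#'
#' @param human_mt,chimp_mt equal-length aligned sequence strings.
#' @return integer vector of 1-based positions where the two differ.
#' @export
informative_sites <- function(human_mt, chimp_mt) {
  if (nchar(human_mt) != nchar(chimp_mt))
    stop("sequences must be aligned to equal length")
  h <- strsplit(human_mt, "")[[1]]
  c_ <- strsplit(chimp_mt, "")[[1]]
  which(h != c_)
}

#' Mitochondrial region annotation table
#'
#' Loads the packaged mtDNA region table (D-loop, hypervariable segments
#' HV1-HV3, replication origins OH/OL, the 13 protein-coding genes, 2 rRNAs
#' and the 22 tRNAs combined), with 1-based inclusive rCRS/MitoMap-convention
#' coordinates. These are configuration data and can be overridden by
#' supplying `path`.
#'
#' @param path optional TSV with columns `region`, `start`, `end`, `strand`,
#'   `type`; defaults to the packaged table.
#' @return data.frame with one row per (possibly multi-part) region interval.
#' @export
mt_region_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mt_regions.tsv", package = "numtatlas")
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("region", "start", "end", "strand", "type")
  if (!all(need %in% names(tab)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  tab
}
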