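#' @title Genome coordinate model and analysis constants
#' @description Chromosome lengths, centromere intervals and autosome flags,
#'   plus the fixed constants shared by every scorer. All coordinates are
#'   1-based, closed intervals; segment length is \code{end - start + 1}.
#' @name genome_reference
NULL

#' Analysis constants
#'
#' Single source of the fixed thresholds used across the pipeline. Any value
#' can be overridden; overrides are validated.
#'
#' @param ... named overrides, e.g. \code{hrd_loh_min_bp = 10e6}.
#' @return A named list with elements:
#' \describe{
#'   \item{hrd_loh_min_bp}{minimum span of a loss-of-heterozygosity (LOH)
#'     event counted by the HRD-LOH score (default 15 Mb).}
#'   \item{lst_min_segment_bp}{minimum span of each region flanking a
#'     large-scale state transition (default 10 Mb).}
#'   \item{lst_max_gap_bp}{maximum gap between the two regions of a
#'     large-scale state transition, also the merge gap (default 3 Mb).}
#'   \item{hrd_phenotype_threshold}{HRD score at or above which a lesion is
#'     called HR-deficient (default 42).}
#'   \item{seem_dominant_ccf}{inclusive relapse CCF above which a surviving
#'     subclone counts as dominant (default 0.45).}
#'   \item{minor_surviving_ccf}{inclusive relapse CCF below which a
#'     surviving subclone counts as minor (default 0.15).}
#'   \item{cosine_match_threshold}{cosine similarity above which a de novo
#'     signature is considered matched to a reference (default 0.70).}
#'   \item{wgd_genome_fraction}{autosomal genome fraction with major copy
#'     number >= 2 that must be exceeded for a whole-genome-doubling call
#'     (default 0.50).}
#'   \item{surviving_min_ccf}{relapse CCF above which a primary subclone is
#'     considered to have survived treatment (default 0.01).}
#' }
#' @export
#' @examples
#' analysis_constants()$hrd_loh_min_bp
#' analysis_constants(hrd_phenotype_threshold = 63)
analysis_constants <- function(...) {
  const <- list(
    hrd_loh_min_bp          = 15e6,
    lst_min_segment_bp      = 10e6,
    lst_max_gap_bp          = 3e6,
    hrd_phenotype_threshold = 42,
    seem_dominant_ccf       = 0.45,
    minor_surviving_ccf     = 0.15,
    cosine_match_threshold  = 0.70,
    wgd_genome_fraction     = 0.50,
    surviving_min_ccf       = 0.01
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("constant overrides must be named")
    unknown <- setdiff(names(overrides), names(const))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "))
    const[names(overrides)] <- overrides
  }
  ccf_keys <- c("seem_dominant_ccf", "minor_surviving_ccf", "surviving_min_ccf")
  for (k in names(const)) {
    v <- const[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("constant '", k, "' must be a single positive finite number")
    if (k %in% ccf_keys && v >= 1)
      stop("constant '", k, "' is a CCF threshold and must lie in (0, 1)")
  }
  const
}

#' Load a chromosome assembly table
#'
#' Reads a TSV with columns \code{chrom}, \code{length}, \code{cen_start},
#' \code{cen_end}, \code{is_autosome} and validates each row: the centromere
#' interval must be strictly inside the chromosome and chromosome names must
#' be unique.
#'
#' @param path path to the assembly TSV.
#' @return A data.frame with one validated row per chromosome and columns
#'   \code{chrom} (character), \code{length}, \code{cen_start},
#'   \code{cen_end} (double bp) and \code{is_autosome} (logical).
#' @export
load_assembly <- function(path) {
  if (!file.exists(path)) stop("assembly file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "length", "cen_start", "cen_end", "is_autosome")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("assembly table missing column(s): ", paste(missing, collapse = ", "))
  tab <- tab[required]
  tab$chrom <- as.character(tab$chrom)
  for (col in c("length", "cen_start", "cen_end"))
    tab[[col]] <- as.numeric(tab[[col]])
  tab$is_autosome <- parse_flag(tab$is_autosome)
  validate_assembly(tab)
}

validate_assembly <- function(tab) {
  if (nrow(tab) == 0L) stop("assembly table is empty")
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    bad <- function(msg) stop("assembly row ", i, " (", r$chrom, "): ", msg)
    if (is.na(r$chrom) || !nzchar(r$chrom)) bad("missing chromosome name")
    if (anyNA(c(r$length, r$cen_start, r$cen_end))) bad("non-numeric field")
    if (is.na(r$is_autosome)) bad("is_autosome not interpretable as a flag")
    if (r$length <= 0) bad("non-positive length")
    if (!(0 < r$cen_start && r$cen_start < r$cen_end && r$cen_end < r$length))
      bad("centromere interval must satisfy 0 < cen_start < cen_end < length")
  }
  if (anyDuplicated(tab$chrom))
    stop("duplicate chromosome name(s): ",
         paste(unique(tab$chrom[duplicated(tab$chrom)]), collapse = ", "))
  if (!any(tab$is_autosome)) stop("assembly has no autosomes")
  rownames(tab) <- NULL
  tab
}

#' Bundled hg19-style assembly
#'
#' The default assembly table shipped with the package: the 22 human
#' autosomes plus chromosome X, with hg19 lengths and centromere intervals.
#' Sex chromosomes are accepted on input but excluded from all scar, CIN and
#' WGD computations.
#'
#' @return assembly data.frame as from [load_assembly()].
#' @export
default_assembly <- function() {
  load_assembly(system.file("extdata", "hg19_assembly.tsv",
                            package = "relapseEvo", mustWork = TRUE))
}

#' Toy three-chromosome assembly for examples and tests
#'
#' Chromosome lengths 100/80/60 Mb with 1 Mb centromeres centered at
#' 50/40/30 Mb; all autosomal.
#'
#' @return assembly data.frame as from [load_assembly()].
#' @export
toy_assembly <- function() {
  validate_assembly(data.frame(
    chrom = c("chr1", "chr2", "chr3"),
    length = c(100e6, 80e6, 60e6),
    cen_start = c(49.5e6, 39.5e6, 29.5e6),
    cen_end = c(50.5e6, 40.5e6, 30.5e6),
    is_autosome = TRUE,
    stringsAsFactors = FALSE
  ))
}

autosomes <- function(assembly) assembly[assembly$is_autosome, , drop = FALSE]

assembly_row <- function(assembly, chrom) {
  i <- match(chrom, assembly$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  assembly[i, , drop = FALSE]
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}
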