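#' @title Genomic scar scores, chromosomal instability and whole-genome doubling
#' @description Scores a [segment_profile()] for the three homologous
#'   recombination deficiency (HRD) scar components and their unweighted sum:
#'   \itemize{
#'     \item HRD-LOH: loss-of-heterozygosity events longer than 15 Mb that do
#'       not cover the whole chromosome;
#'     \item tAI: allelic-imbalance regions reaching a telomere without
#'       crossing the centromere;
#'     \item LST: breakpoints between two regions of at least 10 Mb separated
#'       by less than 3 Mb, computed per chromosome arm.
#'   }
#'   Also computes the fraction of the autosomal genome with non-diploid
#'   total copy number (CIN) and the whole-genome-doubling (WGD) flag.
#'   Only autosomes are scored; sex chromosomes are accepted on input and
#'   dropped here. Uncovered gaps contribute to no score and are excluded
#'   from the CIN/WGD denominators. A run of event segments is broken by an
#'   uncovered gap of \code{lst_max_gap_bp} or more.
#' @name scar_genomics
NULL

seg_len <- function(s) s$end - s$start + 1

#' Merge equal-copy-number adjacent segments
#'
#' Adjacent segments on the same chromosome with identical (major, minor)
#' copy number separated by a gap smaller than \code{lst_max_gap_bp} are
#' merged into one. Idempotent; scoring functions call this internally, so
#' scores are invariant to pre-merging.
#'
#' @param profile a \code{SegmentProfile}.
#' @param constants [analysis_constants()] list.
#' @return The merged \code{SegmentProfile}.
#' @export
merge_segments <- function(profile, constants = analysis_constants()) {
  stopifnot(inherits(profile, "SegmentProfile"))
  seg <- profile$segments
  if (nrow(seg) < 2L) return(profile)
  out <- list()
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    cur <- s[1L, ]
    if (nrow(s) > 1L) for (i in 2L:nrow(s)) {
      nxt <- s[i, ]
      gap <- nxt$start - cur$end - 1
      if (nxt$major_cn == cur$major_cn && nxt$minor_cn == cur$minor_cn &&
          gap < constants$lst_max_gap_bp) {
        cur$end <- nxt$end
        # merged cell_frac: length-weighted mean of the two pieces
        w <- c(seg_len(cur) - seg_len(nxt), seg_len(nxt))
        cur$cell_frac <- sum(c(cur$cell_frac, nxt$cell_frac) * w) / sum(w)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  profile$segments <- do.call(rbind, out)
  rownames(profile$segments) <- NULL
  profile
}

# maximal runs of consecutive segments satisfying `keep`, broken by a
# non-kept segment or by an uncovered gap >= lst_max_gap_bp; returns a list
# of data.frames (each a run, rows in order)
segment_runs <- function(seg, keep, max_gap) {
  runs <- list()
  cur <- integer()
  n <- nrow(seg)
  for (i in seq_len(n)) {
    broken <- length(cur) > 0L &&
      (seg$start[i] - seg$end[cur[length(cur)]] - 1) >= max_gap
    if (!keep[i] || broken) {
      if (length(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- integer()
    }
    if (keep[i]) cur <- c(cur, i)
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  lapply(runs, function(idx) seg[idx, , drop = FALSE])
}

score_chromosomes <- function(profile, assembly, constants, fun) {
  merged <- merge_segments(profile, constants)
  auto <- autosomes(assembly)
  total <- 0L
  for (chrom in unique(merged$segments$chrom)) {
    if (!chrom %in% assembly$chrom) stop("unknown chromosome: ", chrom)
    if (!chrom %in% auto$chrom) next
    s <- merged$segments[merged$segments$chrom == chrom, , drop = FALSE]
    total <- total + fun(s, assembly_row(assembly, chrom))
  }
  total
}

#' HRD-LOH score
#'
#' Number of loss-of-heterozygosity events (maximal runs of segments with
#' minor copy number 0 and major copy number >= 1, where an uncovered gap
#' below \code{lst_max_gap_bp} does not break a run) whose extent (first to
#' last covered base of the run) exceeds \code{hrd_loh_min_bp} and which do
#' not cover the whole chromosome. A run covers the whole chromosome when it
#' spans all of the chromosome's covered extent. Homozygous deletions
#' (major = 0) are not LOH.
#'
#' @param profile a \code{SegmentProfile}.
#' @param assembly assembly table from [load_assembly()].
#' @param constants [analysis_constants()] list.
#' @return integer event count.
#' @export
hrd_loh <- function(profile, assembly, constants = analysis_constants()) {
  score_chromosomes(profile, assembly, constants, function(s, chrom_row) {
    runs <- segment_runs(s, s$minor_cn == 0 & s$major_cn >= 1,
                         constants$lst_max_gap_bp)
    count <- 0L
    for (run in runs) {
      span <- run$end[nrow(run)] - run$start[1L] + 1
      whole <- run$start[1L] == s$start[1L] &&
        run$end[nrow(run)] == s$end[nrow(s)]
      if (span > constants$hrd_loh_min_bp && !whole) count <- count + 1L
    }
    count
  })
}

#' Telomeric allelic imbalance (tAI) score
#'
#' Number of maximal allelic-imbalance runs (major != minor) that include the
#' chromosome's first or last covered base and whose span does not intersect
#' the centromere interval. A single run touching both telomeres necessarily
#' crosses the centromere and counts 0.
#'
#' @inheritParams hrd_loh
#' @return integer event count.
#' @export
tai <- function(profile, assembly, constants = analysis_constants()) {
  score_chromosomes(profile, assembly, constants, function(s, chrom_row) {
    runs <- segment_runs(s, s$major_cn != s$minor_cn,
                         constants$lst_max_gap_bp)
    count <- 0L
    for (run in runs) {
      run_start <- run$start[1L]
      run_end <- run$end[nrow(run)]
      at_telomere <- run_start == s$start[1L] || run_end == s$end[nrow(s)]
      crosses_cen <- run_start <= chrom_row$cen_end &&
        run_end >= chrom_row$cen_start
      if (at_telomere && !crosses_cen) count <- count + 1L
    }
    count
  })
}

# clip a chromosome's segments to one arm; segments wholly inside the
# centromere are dropped, spanning segments are truncated at the boundary
clip_to_arm <- function(s, lo, hi) {
  keep <- s$end >= lo & s$start <= hi
  s <- s[keep, , drop = FALSE]
  s$start <- pmax(s$start, lo)
  s$end <- pmin(s$end, hi)
  s
}

#' Large-scale state transition (LST) score
#'
#' Number of breakpoints between adjacent regions (per chromosome arm, after
#' merging and splitting segments at the centromere) where both regions span
#' at least \code{lst_min_segment_bp}, the gap between them is smaller than
#' \code{lst_max_gap_bp}, and the two regions differ in allele-specific copy
#' number.
#'
#' @inheritParams hrd_loh
#' @return integer breakpoint count.
#' @export
lst <- function(profile, assembly, constants = analysis_constants()) {
  score_chromosomes(profile, assembly, constants, function(s, chrom_row) {
    arms <- list(clip_to_arm(s, 1, chrom_row$cen_start - 1),
                 clip_to_arm(s, chrom_row$cen_end + 1, chrom_row$length))
    count <- 0L
    for (arm in arms) {
      if (nrow(arm) < 2L) next
      for (i in 2L:nrow(arm)) {
        a <- arm[i - 1L, ]; b <- arm[i, ]
        gap <- b$start - a$end - 1
        differs <- a$major_cn != b$major_cn || a$minor_cn != b$minor_cn
        if (differs && gap < constants$lst_max_gap_bp &&
            seg_len(a) >= constants$lst_min_segment_bp &&
            seg_len(b) >= constants$lst_min_segment_bp)
          count <- count + 1L
      }
    }
    count
  })
}

#' Fraction of the autosomal genome with non-diploid total copy number
#'
#' Sum of autosomal bp with \code{major + minor != 2}, divided by the total
#' autosomal bp covered by segments. A tetraploid (2,2) genome scores 1.
#'
#' @inheritParams hrd_loh
#' @return fraction in [0, 1].
#' @export
cin_fraction <- function(profile, assembly, constants = analysis_constants()) {
  auto <- autosomes(assembly)
  seg <- profile$segments
  seg <- seg[seg$chrom %in% auto$chrom, , drop = FALSE]
  unknown <- setdiff(profile$segments$chrom, assembly$chrom)
  if (length(unknown)) stop("unknown chromosome: ", unknown[1L])
  if (!nrow(seg)) return(0)
  lens <- seg_len(seg)
  sum(lens[seg$major_cn + seg$minor_cn != 2]) / sum(lens)
}

#' Whole-genome doubling flag
#'
#' TRUE iff strictly more than \code{wgd_genome_fraction} of the covered
#' autosomal genome (bp-weighted) has major copy number >= 2.
#'
#' @inheritParams hrd_loh
#' @return logical flag.
#' @export
detect_wgd <- function(profile, assembly, constants = analysis_constants()) {
  auto <- autosomes(assembly)
  seg <- profile$segments
  unknown <- setdiff(seg$chrom, assembly$chrom)
  if (length(unknown)) stop("unknown chromosome: ", unknown[1L])
  seg <- seg[seg$chrom %in% auto$chrom, , drop = FALSE]
  if (!nrow(seg)) return(FALSE)
  lens <- seg_len(seg)
  sum(lens[seg$major_cn >= 2]) / sum(lens) > constants$wgd_genome_fraction
}

#' HRD phenotype call
#'
#' A lesion has the HRD phenotype when its HRD score reaches
#' \code{hrd_phenotype_threshold} (>= 42) or it carries a bi-allelic
#' BRCA1/2 alteration.
#'
#' @param hrd_score_value numeric HRD score (HRD-LOH + tAI + LST).
#' @param biallelic_brca logical, bi-allelic BRCA1/2 alteration present.
#' @param constants [analysis_constants()] list.
#' @return logical flag.
#' @export
classify_hrd_phenotype <- function(hrd_score_value, biallelic_brca = FALSE,
                                   constants = analysis_constants()) {
  isTRUE(hrd_score_value >= constants$hrd_phenotype_threshold) ||
    isTRUE(biallelic_brca)
}

#' Score one segment profile
#'
#' Computes all scar components, the combined HRD score (their unweighted
#' sum), CIN fraction, WGD flag and the HRD phenotype call.
#'
#' @inheritParams hrd_loh
#' @param biallelic_brca logical, bi-allelic BRCA1/2 alteration in this
#'   lesion (feeds the phenotype call only).
#' @return A list of class \code{ScarResult} with elements \code{sample_id},
#'   \code{lesion}, \code{hrd_loh}, \code{tai}, \code{lst},
#'   \code{hrd_score}, \code{cin_fraction}, \code{wgd},
#'   \code{hrd_phenotype}.
#' @export
score_profile <- function(profile, assembly, biallelic_brca = FALSE,
                          constants = analysis_constants()) {
  loh <- hrd_loh(profile, assembly, constants)
  tai_n <- tai(profile, assembly, constants)
  lst_n <- lst(profile, assembly, constants)
  score <- loh + tai_n + lst_n
  structure(list(
    sample_id = profile$sample_id,
    lesion = profile$lesion,
    hrd_loh = loh, tai = tai_n, lst = lst_n, hrd_score = score,
    cin_fraction = cin_fraction(profile, assembly, constants),
    wgd = detect_wgd(profile, assembly, constants),
    hrd_phenotype = classify_hrd_phenotype(score, biallelic_brca, constants)
  ), class = "ScarResult")
}

#' Score many profiles into a table
#'
#' @param profiles named list of \code{SegmentProfile}s.
#' @param assembly assembly table.
#' @param biallelic_brca named logical vector by sample id (default all
#'   FALSE).
#' @param constants [analysis_constants()] list.
#' @return data.frame with one row per sample.
#' @export
score_cohort <- function(profiles, assembly,
                         biallelic_brca = NULL,
                         constants = analysis_constants()) {
  rows <- lapply(profiles, function(p) {
    bb <- isTRUE(biallelic_brca[[p$sample_id]])
    r <- score_profile(p, assembly, bb, constants)
    data.frame(sample = r$sample_id, lesion = r$lesion,
               hrd_loh = r$hrd_loh, tai = r$tai, lst = r$lst,
               hrd_score = r$hrd_score, cin_fraction = r$cin_fraction,
               wgd = r$wgd, hrd_phenotype = r$hrd_phenotype,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
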