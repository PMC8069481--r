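# Independent brute-force oracles. These deliberately use a different
# representation from the package (per-megabase bins instead of segment
# tables) so scorer and oracle share no code path.

MB <- 1e6

# assembly with megabase-aligned centromeres so bin-scale oracles are exact
oracle_assembly <- function() {
  relapseEvo:::validate_assembly(data.frame(
    chrom = c("chr1", "chr2", "chr3"),
    length = c(100, 80, 60) * MB,
    cen_start = c(45, 36, 27) * MB + 1,
    cen_end = c(48, 39, 30) * MB,
    is_autosome = TRUE,
    stringsAsFactors = FALSE
  ))
}

# random megabase-aligned profile: pieces with weighted copy-number states,
# some pieces left uncovered
random_profile <- function(assembly, seed) {
  states <- list(c(1, 1), c(1, 0), c(2, 1), c(2, 0), c(2, 2), c(3, 1),
                 c(3, 2), c(0, 0), c(4, 2))
  w <- c(3, 2, 2, 1, 1, 1, 1, 0.5, 0.5)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(assembly))) {
    len_mb <- assembly$length[i] / MB
    k <- sample(1:8, 1L)
    cuts <- sort(sample(seq_len(len_mb - 1L), k - 1L))
    bounds <- c(0L, cuts, len_mb)
    for (j in seq_len(k)) {
      if (stats::runif(1L) > 0.85) next  # uncovered gap
      cn <- states[[sample(seq_along(states), 1L, prob = w)]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = assembly$chrom[i],
        start = bounds[j] * MB + 1, end = bounds[j + 1L] * MB,
        major_cn = cn[1L], minor_cn = cn[2L], cell_frac = 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  segment_profile(paste0("rand", seed), do.call(rbind, rows))
}

# bin matrix for one chromosome: columns major/minor, NA when uncovered
chrom_bins <- function(profile, assembly, chrom) {
  len_mb <- assembly$length[match(chrom, assembly$chrom)] / MB
  bins <- matrix(NA_real_, nrow = len_mb, ncol = 2L)
  s <- profile$segments[profile$segments$chrom == chrom, , drop = FALSE]
  for (j in seq_len(nrow(s))) {
    lo <- (s$start[j] - 1) / MB + 1
    hi <- s$end[j] / MB
    bins[lo:hi, 1L] <- s$major_cn[j]
    bins[lo:hi, 2L] <- s$minor_cn[j]
  }
  bins
}

# maximal runs of bins satisfying `keep`; an uncovered stretch of gap_mb or
# more bins breaks a run, a covered non-kept bin always does
bin_runs <- function(bins, keep, gap_mb = 3L) {
  covered <- !is.na(bins[, 1L])
  runs <- list()
  first <- NA_integer_; last <- NA_integer_
  flush <- function() {
    if (!is.na(first)) runs[[length(runs) + 1L]] <<- c(first, last)
    first <<- NA_integer_; last <<- NA_integer_
  }
  for (i in seq_len(nrow(bins))) {
    if (!covered[i]) next                 # gap judged when a run resumes
    if (!keep[i]) { flush(); next }
    if (!is.na(last) && (i - last - 1L) >= gap_mb) flush()
    if (is.na(first)) first <- i
    last <- i
  }
  flush()
  runs
}

oracle_hrd_loh <- function(profile, assembly) {
  total <- 0L
  for (chrom in unique(profile$segments$chrom)) {
    bins <- chrom_bins(profile, assembly, chrom)
    covered <- which(!is.na(bins[, 1L]))
    if (!length(covered)) next
    keep <- !is.na(bins[, 1L]) & bins[, 2L] == 0 & bins[, 1L] >= 1
    for (run in bin_runs(bins, keep)) {
      extent_mb <- run[2L] - run[1L] + 1L
      whole <- run[1L] == min(covered) && run[2L] == max(covered)
      if (extent_mb * MB > 15 * MB && !whole) total <- total + 1L
    }
  }
  total
}

oracle_tai <- function(profile, assembly) {
  total <- 0L
  for (chrom in unique(profile$segments$chrom)) {
    a <- assembly[match(chrom, assembly$chrom), ]
    bins <- chrom_bins(profile, assembly, chrom)
    covered <- which(!is.na(bins[, 1L]))
    if (!length(covered)) next
    keep <- !is.na(bins[, 1L]) & bins[, 1L] != bins[, 2L]
    for (run in bin_runs(bins, keep)) {
      run_start_bp <- (run[1L] - 1L) * MB + 1
      run_end_bp <- run[2L] * MB
      telomeric <- run[1L] == min(covered) || run[2L] == max(covered)
      crosses <- run_start_bp <= a$cen_end && run_end_bp >= a$cen_start
      if (telomeric && !crosses) total <- total + 1L
    }
  }
  total
}

oracle_lst <- function(profile, assembly) {
  total <- 0L
  for (chrom in unique(profile$segments$chrom)) {
    a <- assembly[match(chrom, assembly$chrom), ]
    bins <- chrom_bins(profile, assembly, chrom)
    arm_ranges <- list(c(1L, (a$cen_start - 1) / MB),
                       c(a$cen_end / MB + 1L, a$length / MB))
    for (ar in arm_ranges) {
      arm <- bins[ar[1L]:ar[2L], , drop = FALSE]
      # blocks: constant-CN stretches; a same-CN resume over a gap < 3 Mb
      # continues the block (gap absorbed), anything else starts a new one
      blocks <- list()
      cur <- NULL
      gap <- 0L
      for (i in seq_len(nrow(arm))) {
        if (is.na(arm[i, 1L])) { gap <- gap + 1L; next }
        cn <- arm[i, ]
        if (!is.null(cur) && all(cur$cn == cn) && gap < 3L) {
          cur$last <- i
        } else {
          if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
          cur <- list(cn = cn, first = i, last = i, gap_before = gap)
        }
        gap <- 0L
      }
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
      if (length(blocks) >= 2L) for (b in 2L:length(blocks)) {
        left <- blocks[[b - 1L]]; right <- blocks[[b]]
        len_l <- left$last - left$first + 1L
        len_r <- right$last - right$first + 1L
        if (any(left$cn != right$cn) && right$gap_before < 3L &&
            len_l >= 10L && len_r >= 10L)
          total <- total + 1L
      }
    }
  }
  total
}

# hand-enumerated allelic-status oracle over event counts
oracle_allelic_status <- function(g_lof, g_vus, s_lof, s_vus, s_loh, deep) {
  lof_biallelic <- (g_lof >= 1 && s_loh >= 1) || (g_lof >= 1 && s_lof >= 1) ||
    (s_lof >= 1 && s_loh >= 1) || s_lof >= 2 || deep >= 1
  vus_biallelic <- (g_lof >= 1 && s_vus >= 1) || (s_lof >= 1 && s_vus >= 1) ||
    (s_vus >= 1 && s_loh >= 1)
  if (lof_biallelic) "biallelic_lof"
  else if (vus_biallelic) "biallelic_vus"
  else if (g_lof >= 1 || s_lof >= 1 || s_vus >= 1) "monoallelic"
  else "none"
}

# exact one-sided signed-rank p-value by explicit enumeration of all 2^n
# sign assignments
oracle_signed_rank_p <- function(primary, relapse) {
  d <- relapse - primary
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  mean(W_all >= W_obs)
}

# events table builder for hr_pathway tests
hr_events <- function(gene, ...) {
  ev <- c(...)
  if (!length(ev))
    return(data.frame(sample = character(), lesion = character(),
                      gene = character(), event = character(),
                      stringsAsFactors = FALSE))
  data.frame(sample = "s1", lesion = "primary", gene = gene, event = ev,
             stringsAsFactors = FALSE)
}

# shared 20-lesion exposure design for NMF recovery tests: spans the
# 3-signature simplex and includes near-pure anchor lesions
nmf_design_weights <- function() {
  rbind(c(.9, .05, .05), c(.05, .9, .05), c(.05, .05, .9),
        c(.8, .1, .1), c(.1, .8, .1), c(.1, .1, .8),
        c(.6, .2, .2), c(.2, .6, .2), c(.2, .2, .6),
        c(.5, .3, .2), c(.3, .5, .2), c(.2, .3, .5),
        c(.4, .4, .2), c(.4, .2, .4), c(.2, .4, .4),
        c(.7, .15, .15), c(.15, .7, .15), c(.15, .15, .7),
        c(.33, .33, .34), c(.45, .1, .45))
}

nmf_cohort_catalog <- function(seed, burden = 3000) {
  W <- nmf_design_weights()
  muts <- do.call(rbind, lapply(seq_len(nrow(W)), function(i)
    simulate_mutations(W[i, ], burden, seed = seed * 1000 + i,
                       sample_id = sprintf("S%02d", i))))
  build_catalog(muts)
}

extdata <- function(name)
  system.file("extdata", name, package = "relapseEvo", mustWork = TRUE)
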