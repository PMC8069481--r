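#' @title Synthetic primary/relapse cohort generator
#' @description Generates paired primary/relapse patients with a full
#'   ground-truth ledger: allele-specific copy-number profiles with exact
#'   planted scar-event counts, clone trees realizing the three evolution
#'   models, mutation catalogs drawn from mixtures of an age-like, an
#'   APOBEC-like and a flat signature, and HR-gene variant tables covering
#'   every bi-allelic mechanism. Every planted quantity is recoverable by
#'   the downstream scoring modules, which makes the whole pipeline testable
#'   without protected sequencing data.
#'
#'   Scar events are planted non-overlapping, separated by baseline copy
#'   number, with telomeric-imbalance events abutting a telomere and
#'   LOH events strictly interstitial, so planted counts are exact rather
#'   than approximate.
#' @name synthetic_cohort
NULL

# event-block geometry, derived from the constants so that scaled-down toy
# worlds stay consistent: spacer segments are < lst_min_segment_bp so a
# planted block never creates an accidental large-scale state transition
event_geometry <- function(constants) {
  list(spacer = constants$lst_min_segment_bp / 2,
       loh_len = function() round(stats::runif(
         1L, constants$hrd_loh_min_bp * 1.05, constants$hrd_loh_min_bp * 1.6)),
       lst_len = function() round(stats::runif(
         1L, constants$lst_min_segment_bp, constants$lst_min_segment_bp * 1.4)),
       tai_len = function() round(stats::runif(
         1L, 0.5, 0.9) * constants$lst_min_segment_bp),
       lead = function() round(stats::runif(
         1L, constants$lst_max_gap_bp, 2 * constants$lst_max_gap_bp)))
}

# copy-number tuples relative to the baseline (M, m): chosen pairwise
# distinct so adjacent planted segments never merge
event_cn <- function(base, kind) {
  M <- base[1L]; m <- base[2L]
  switch(kind,
         loh    = c(M, 0),           # LOH, allelic imbalance, interstitial
         tai    = c(M + 1, m),       # imbalance, planted at a telomere
         lst_a  = c(M + 1, m + 1),   # balanced, differs from baseline
         lst_b  = c(M + 2, m + 1),   # differs from lst_a: 1 breakpoint
         spacer = c(M + 3, m))       # short shield around a block
}

#' Simulate one allele-specific copy-number profile with planted scar events
#'
#' Plants exactly \code{n_loh} interstitial LOH events (> 15 Mb, minor copy
#' number 0), \code{n_tai} telomeric allelic-imbalance events (< 10 Mb,
#' abutting a telomere, not reaching the centromere) and \code{n_lst}
#' large-scale state transitions (two abutting >= 10 Mb regions differing in
#' copy number, shielded by short spacer segments) on a diploid baseline, or
#' a tetraploid (2,2) baseline when \code{wgd} is TRUE. The whole assembly
#' is covered by segments.
#'
#' @param assembly assembly table from [load_assembly()]; only autosomes
#'   receive events.
#' @param n_loh,n_tai,n_lst non-negative planted event counts.
#' @param wgd logical; plant on a genome-doubled baseline.
#' @param seed integer seed (profile is a pure function of its arguments).
#' @param sample_id,lesion passed to [segment_profile()].
#' @param purity tumor purity.
#' @param constants [analysis_constants()] list; event geometry scales with
#'   the thresholds, so scorers run with the same constants recover the
#'   planted counts exactly.
#' @return a \code{SegmentProfile} whose scar scores are exactly the
#'   planted counts.
#' @export
simulate_profile <- function(assembly, n_loh = 0L, n_tai = 0L, n_lst = 0L,
                             wgd = FALSE, seed = 1L,
                             sample_id = "synthetic", lesion = NA_character_,
                             purity = 0.8, constants = analysis_constants()) {
  stopifnot(n_loh >= 0, n_tai >= 0, n_lst >= 0)
  geom <- event_geometry(constants)
  SPACER_BP <- geom$spacer
  with_seed(seed, {
    auto <- autosomes(assembly)
    base <- if (wgd) c(2, 2) else c(1, 1)
    # arms: one row per chromosome arm with its telomere side
    arms <- do.call(rbind, lapply(seq_len(nrow(auto)), function(i) {
      r <- auto[i, ]
      data.frame(chrom = r$chrom,
                 lo = c(1, r$cen_end + 1),
                 hi = c(r$cen_start - 1, r$length),
                 side = c("p", "q"), stringsAsFactors = FALSE)
    }))
    arms$cursor <- arms$lo      # next free position (from the lo side)
    arms$eff_hi <- arms$hi      # hi shrinks when a q-telomere tAI is placed
    arms$has_tai <- FALSE
    placed <- list()
    add_seg <- function(chrom, start, end, cn, cf = 1) {
      placed[[length(placed) + 1L]] <<- data.frame(
        chrom = chrom, start = start, end = end,
        major_cn = cn[1L], minor_cn = cn[2L], cell_frac = cf,
        stringsAsFactors = FALSE)
    }
    gap_bp <- geom$lead
    # --- telomeric allelic imbalance events, one per free telomere
    if (n_tai > nrow(arms))
      stop("assembly too small: ", n_tai, " tAI events but only ",
           nrow(arms), " telomeres")
    if (n_tai > 0) for (k in seq_len(n_tai)) {
      free <- which(!arms$has_tai)
      a <- free[which.max(arms$eff_hi[free] - arms$cursor[free])]
      len <- geom$tai_len()
      if (arms$eff_hi[a] - arms$cursor[a] < len + SPACER_BP)
        stop("assembly too small for requested tAI events")
      if (arms$side[a] == "p") {
        add_seg(arms$chrom[a], arms$lo[a], arms$lo[a] + len - 1,
                event_cn(base, "tai"))
        arms$cursor[a] <- arms$lo[a] + len
      } else {
        add_seg(arms$chrom[a], arms$hi[a] - len + 1, arms$hi[a],
                event_cn(base, "tai"))
        arms$eff_hi[a] <- arms$hi[a] - len
      }
      arms$has_tai[a] <- TRUE
    }
    # --- interstitial blocks (LOH events and LST pairs)
    blocks <- c(rep("loh", n_loh), rep("lst", n_lst))
    for (kind in blocks) {
      widths <- if (kind == "loh") {
        c(SPACER_BP, geom$loh_len(), SPACER_BP)
      } else {
        c(SPACER_BP, geom$lst_len(), geom$lst_len(), SPACER_BP)
      }
      cns <- if (kind == "loh") {
        list(event_cn(base, "spacer"), event_cn(base, "loh"),
             event_cn(base, "spacer"))
      } else {
        list(event_cn(base, "spacer"), event_cn(base, "lst_a"),
             event_cn(base, "lst_b"), event_cn(base, "spacer"))
      }
      lead <- gap_bp()
      need <- lead + sum(widths) + SPACER_BP  # trailing baseline guaranteed
      free <- arms$eff_hi - arms$cursor + 1
      a <- which.max(free)
      if (free[a] < need)
        stop("assembly too small for requested ", kind, " events")
      pos <- arms$cursor[a] + lead
      for (j in seq_along(widths)) {
        add_seg(arms$chrom[a], pos, pos + widths[j] - 1, cns[[j]])
        pos <- pos + widths[j]
      }
      arms$cursor[a] <- pos
    }
    # --- fill everything else with baseline copy number
    seg <- do.call(rbind, c(list(data.frame(chrom = character(),
                                            start = numeric(), end = numeric(),
                                            major_cn = numeric(),
                                            minor_cn = numeric(),
                                            cell_frac = numeric())), placed))
    filled <- list()
    for (i in seq_len(nrow(auto))) {
      chrom <- auto$chrom[i]
      len <- auto$length[i]
      s <- seg[seg$chrom == chrom, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      cursor <- 1
      for (j in seq_len(nrow(s))) {
        if (s$start[j] > cursor)
          filled[[length(filled) + 1L]] <- data.frame(
            chrom = chrom, start = cursor, end = s$start[j] - 1,
            major_cn = base[1L], minor_cn = base[2L], cell_frac = 1,
            stringsAsFactors = FALSE)
        filled[[length(filled) + 1L]] <- s[j, ]
        cursor <- s$end[j] + 1
      }
      if (cursor <= len)
        filled[[length(filled) + 1L]] <- data.frame(
          chrom = chrom, start = cursor, end = len,
          major_cn = base[1L], minor_cn = base[2L], cell_frac = 1,
          stringsAsFactors = FALSE)
    }
    segment_profile(sample_id, do.call(rbind, filled), lesion = lesion,
                    purity = purity, ploidy = if (wgd) 4 else 2)
  })
}

round4 <- function(x) round(x, 4)

#' Simulate a clone tree realizing one evolution model
#'
#' Emits a \code{TreeDocument} with a normal root (node \code{"0"}), a
#' founder clone (node \code{"1"}, CCF 1 in both lesions) and
#' model-specific subclones:
#' \describe{
#'   \item{DNSEM}{primary subclones are eradicated (relapse CCF 0); relapse
#'     subclones emerge de novo from the founder.}
#'   \item{HRDEM}{one minor primary subclone survives with inclusive relapse
#'     CCF < 0.15 while a dominant relapse-specific clone emerges; the
#'     relapse lesion carries the HRD phenotype (see the returned truth).}
#'   \item{SEEM}{one primary subclone survives and expands to inclusive
#'     relapse CCF > 0.45, spawning child clones.}
#' }
#'
#' @param model \code{"DNSEM"}, \code{"HRDEM"} or \code{"SEEM"}.
#' @param seed integer seed.
#' @param patient_id patient identifier.
#' @return list with \code{tree} (a \code{TreeDocument}) and
#'   \code{relapse_hrd} (logical ground truth used by the classifier).
#' @export
simulate_tree <- function(model = c("DNSEM", "HRDEM", "SEEM"), seed = 1L,
                          patient_id = "synthetic") {
  model <- match.arg(model)
  with_seed(seed, {
    nodes <- data.frame(id = c("0", "1"), parent = c(NA, "0"),
                        ccf_primary = c(1, 1), ccf_relapse = c(1, 1),
                        stringsAsFactors = FALSE)
    nid <- 1L
    new_node <- function(parent, pr, re) {
      nid <<- nid + 1L
      nodes[nrow(nodes) + 1L, ] <<- list(as.character(nid), parent,
                                         round4(pr), round4(re))
      as.character(nid)
    }
    relapse_hrd <- FALSE
    if (model == "DNSEM") {
      # doomed primary subclones, relapse subclones emerge from the founder
      k <- sample(1:3, 1L)
      ccfs <- stats::runif(k, 0.1, 0.8 / k)
      for (ccf in ccfs) new_node("1", ccf, 0)
      r1 <- new_node("1", 0, stats::runif(1L, 0.5, 0.9))
      if (stats::runif(1L) < 0.5)
        new_node(r1, 0, stats::runif(1L, 0.1, 0.4))
    } else if (model == "HRDEM") {
      surv <- new_node("1", stats::runif(1L, 0.1, 0.35),
                       stats::runif(1L, 0.03, 0.12))
      new_node("1", stats::runif(1L, 0.1, 0.3), 0)       # eradicated
      dom <- new_node("1", 0, stats::runif(1L, 0.6, 0.8)) # dominant relapse
      if (stats::runif(1L) < 0.5)
        new_node(dom, 0, stats::runif(1L, 0.1, 0.5))
      relapse_hrd <- TRUE
    } else { # SEEM
      surv_re <- stats::runif(1L, 0.5, 0.9)
      surv <- new_node("1", stats::runif(1L, 0.1, 0.35), surv_re)
      new_node(surv, 0, stats::runif(1L, 0.2, 0.9) * surv_re)  # child clone
      new_node("1", stats::runif(1L, 0.1, 0.3), 0)             # eradicated
    }
    assignments <- c(alt_trunk = "1",
                     alt_branch = nodes$id[nrow(nodes)])
    list(tree = tree_document(patient_id, nodes,
                              samples = c("primary", "relapse"),
                              assignments = assignments),
         relapse_hrd = relapse_hrd)
  })
}

context_parts <- function(label) {
  # "A[C>T]G" -> five_prime, ref, alt, three_prime
  list(five_prime = substr(label, 1L, 1L),
       ref = substr(label, 3L, 3L),
       alt = substr(label, 5L, 5L),
       three_prime = substr(label, 7L, 7L))
}

#' Simulate somatic mutations from a signature mixture
#'
#' Draws \code{burden} single-base substitutions whose trinucleotide
#' contexts follow the mixture of the three bundled reference signatures
#' (age-like, APOBEC-like, flat). Half of the records, in expectation, are
#' reported on the purine strand to exercise strand collapsing downstream.
#'
#' @param weights length-3 non-negative mixture weights (age-like,
#'   APOBEC-like, flat), summing to 1.
#' @param burden number of mutations.
#' @param seed integer seed.
#' @param sample_id,lesion record fields.
#' @param genes gene symbol pool to draw from.
#' @return mutation data.frame in the [read_mutations()] layout.
#' @export
simulate_mutations <- function(weights, burden, seed = 1L,
                               sample_id = "synthetic", lesion = "primary",
                               genes = sprintf("GENE%02d", 1:40)) {
  stopifnot(length(weights) == 3L)
  if (any(weights < 0)) stop("negative signature weight")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  empty <- data.frame(sample = character(), lesion = character(),
                      gene = character(), variant_class = character(),
                      origin = character(), ref = character(),
                      alt = character(), five_prime = character(),
                      three_prime = character(), stringsAsFactors = FALSE)
  if (burden == 0) return(empty)
  with_seed(seed, {
    sigs <- reference_signatures()
    labels <- context_labels()
    which_sig <- sample.int(3L, burden, replace = TRUE, prob = weights)
    ctx <- character(burden)
    for (s in 1:3) {
      idx <- which_sig == s
      if (any(idx))
        ctx[idx] <- sample(labels, sum(idx), replace = TRUE,
                           prob = sigs[, s])
    }
    parts <- lapply(ctx, context_parts)
    ref <- vapply(parts, `[[`, "", "ref")
    alt <- vapply(parts, `[[`, "", "alt")
    p5 <- vapply(parts, `[[`, "", "five_prime")
    p3 <- vapply(parts, `[[`, "", "three_prime")
    flip <- stats::runif(burden) < 0.5
    if (any(flip)) {
      new5 <- revcomp_base(p3[flip])
      p3[flip] <- revcomp_base(p5[flip])
      p5[flip] <- new5
      ref[flip] <- revcomp_base(ref[flip])
      alt[flip] <- revcomp_base(alt[flip])
    }
    data.frame(
      sample = sample_id, lesion = lesion,
      gene = sample(genes, burden, replace = TRUE),
      variant_class = sample(c("missense", "silent", "other"), burden,
                             replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      origin = "somatic", ref = unname(ref), alt = unname(alt),
      five_prime = unname(p5), three_prime = unname(p3),
      stringsAsFactors = FALSE)
  })
}

# HR-variant scenarios planted across the cohort: the 8 bi-allelic
# mechanisms plus a monoallelic progression and a quiet patient. Each entry
# gives the events per lesion; "both" rows are emitted in both lesions
# (germline events always are).
hr_scenarios <- function() {
  list(
    list(name = "mech1_progression", gene = "WRN",
         primary = c("germline_lof"),
         relapse = c("germline_lof", "somatic_loh"),
         expected_relapse = "biallelic_lof"),
    list(name = "mech2", gene = "BRCA2",
         primary = c("germline_lof", "somatic_lof"),
         relapse = c("germline_lof", "somatic_lof"),
         expected_relapse = "biallelic_lof"),
    list(name = "mech3", gene = "ATM",
         primary = c("somatic_lof"),
         relapse = c("somatic_lof", "somatic_loh"),
         expected_relapse = "biallelic_lof"),
    list(name = "mech4", gene = "PALB2",
         primary = character(),
         relapse = c("somatic_lof", "somatic_lof"),
         expected_relapse = "biallelic_lof"),
    list(name = "mech5", gene = "BRCA1",
         primary = c("deep_deletion"),
         relapse = c("deep_deletion"),
         expected_relapse = "biallelic_lof"),
    list(name = "mech6", gene = "FANCM",
         primary = c("germline_lof"),
         relapse = c("germline_lof", "somatic_vus"),
         expected_relapse = "biallelic_vus"),
    list(name = "mech7", gene = "CHEK2",
         primary = character(),
         relapse = c("somatic_lof", "somatic_vus"),
         expected_relapse = "biallelic_vus"),
    list(name = "mech8", gene = "RAD51C",
         primary = c("somatic_vus"),
         relapse = c("somatic_vus", "somatic_loh"),
         expected_relapse = "biallelic_vus"),
    list(name = "monoallelic", gene = "BLM",
         primary = c("germline_lof"),
         relapse = c("germline_lof"),
         expected_relapse = "monoallelic"),
    list(name = "quiet", gene = NA_character_,
         primary = character(), relapse = character(),
         expected_relapse = "none")
  )
}

#' Cohort simulation parameters
#'
#' The defaults state the simulated world: 10 patients, model mix matching
#' the observed 4/3/3 split, relapse mutation burden about 57\% above the
#' primary burden, per-model scar-event counts keeping relapse lesions of
#' the HRD evolution model at HRD score >= 42, and per-model signature
#' mixtures shifting from age-like toward APOBEC-like at relapse.
#'
#' @param n_patients number of patients.
#' @param model_mix named probabilities over DNSEM/HRDEM/SEEM (sums to 1).
#' @param seed master seed; each patient derives a private stream from it.
#' @return list of class \code{SimulationParams}.
#' @export
simulation_params <- function(n_patients = 10L,
                              model_mix = c(DNSEM = 0.4, HRDEM = 0.3,
                                            SEEM = 0.3),
                              seed = 1L) {
  stopifnot(n_patients >= 0)
  if (abs(sum(model_mix) - 1) > 1e-9) stop("model_mix must sum to 1")
  if (!setequal(names(model_mix), c("DNSEM", "HRDEM", "SEEM")))
    stop("model_mix must be named DNSEM/HRDEM/SEEM")
  structure(list(
    n_patients = as.integer(n_patients),
    model_mix = model_mix[c("DNSEM", "HRDEM", "SEEM")],
    seed = as.integer(seed),
    # planted scar-event count ranges [lo, hi] per model and lesion
    scar_ranges = list(
      DNSEM = list(primary = c(1, 4), relapse = c(2, 6)),
      HRDEM = list(primary = c(2, 5), relapse = c(14, 16)),
      SEEM  = list(primary = c(1, 4), relapse = c(2, 6))),
    burden_primary = c(1000, 2000),
    relapse_burden_factor = c(1.3, 1.9),   # mean ~1.57
    signature_weights = list(
      DNSEM = list(primary = c(0.65, 0.15, 0.20),
                   relapse = c(0.35, 0.30, 0.35)),
      HRDEM = list(primary = c(0.60, 0.20, 0.20),
                   relapse = c(0.25, 0.45, 0.30)),
      SEEM  = list(primary = c(0.30, 0.50, 0.20),
                   relapse = c(0.20, 0.60, 0.20)))
  ), class = "SimulationParams")
}

patient_seed <- function(master_seed, index) {
  # stays well below .Machine$integer.max even after small offsets
  (as.numeric(master_seed) * 7919 + index * 104729) %% 2e9
}

#' Simulate a full paired cohort with ground truth
#'
#' For each patient: draws an evolution model from the mix, plants
#' per-lesion scar events, simulates the clone tree, mutation catalogs and
#' HR-variant scenario, and records everything in a truth ledger. With
#' \code{out_dir} set, writes \code{segments.tsv}, \code{mutations.tsv},
#' \code{hr_variants.tsv}, \code{trees/<patient>.json} and
#' \code{truth.json}; re-running with the same parameters is byte-identical.
#'
#' @param params a [simulation_params()] object.
#' @param assembly assembly table (default [default_assembly()]).
#' @param out_dir optional output directory.
#' @return list of class \code{CohortBundle}: \code{profiles} (named list),
#'   \code{trees}, \code{mutations} (one data.frame), \code{hr_variants},
#'   \code{truth} (per-patient ledger list), \code{params}.
#' @export
simulate_cohort <- function(params = simulation_params(),
                            assembly = default_assembly(),
                            out_dir = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  profiles <- list(); trees <- list(); truth <- list()
  mutations <- list(); hr_rows <- list()
  scenarios <- hr_scenarios()
  models <- if (params$n_patients > 0)
    with_seed(params$seed,
              sample(names(params$model_mix), params$n_patients,
                     replace = TRUE, prob = params$model_mix))
  else character()
  for (i in seq_len(params$n_patients)) {
    pid <- sprintf("BC%02d", i)
    pseed <- patient_seed(params$seed, i)
    model <- models[i]
    scn <- scenarios[[(i - 1L) %% length(scenarios) + 1L]]
    draws <- with_seed(pseed, {
      rng <- function(r) sample(seq(r[1L], r[2L]), 3L, replace = TRUE)
      sc <- params$scar_ranges[[model]]
      burden_p <- round(stats::runif(1L, params$burden_primary[1L],
                                     params$burden_primary[2L]))
      fac <- stats::runif(1L, params$relapse_burden_factor[1L],
                          params$relapse_burden_factor[2L])
      list(scar_primary = rng(sc$primary), scar_relapse = rng(sc$relapse),
           burden_p = burden_p, burden_r = round(burden_p * fac),
           wgd = stats::runif(1L) < 0.1)
    })
    sim_tree <- simulate_tree(model, seed = pseed + 1, patient_id = pid)
    lesions <- list(
      primary = list(scar = draws$scar_primary, burden = draws$burden_p,
                     weights = params$signature_weights[[model]]$primary),
      relapse = list(scar = draws$scar_relapse, burden = draws$burden_r,
                     weights = params$signature_weights[[model]]$relapse))
    for (lesion in names(lesions)) {
      l <- lesions[[lesion]]
      sid <- paste0(pid, "_", lesion)
      profiles[[sid]] <- simulate_profile(
        assembly, n_loh = l$scar[1L], n_tai = l$scar[2L],
        n_lst = l$scar[3L], wgd = draws$wgd && lesion == "relapse",
        seed = pseed + if (lesion == "primary") 2 else 3,
        sample_id = sid, lesion = lesion)
      mutations[[sid]] <- simulate_mutations(
        l$weights, l$burden,
        seed = pseed + if (lesion == "primary") 4 else 5,
        sample_id = sid, lesion = lesion)
      if (!is.na(scn$gene) && length(scn[[lesion]]))
        hr_rows[[sid]] <- data.frame(
          sample = sid, lesion = lesion, gene = scn$gene,
          event = scn[[lesion]], stringsAsFactors = FALSE)
    }
    trees[[pid]] <- sim_tree$tree
    truth[[pid]] <- list(
      patient_id = pid, model = model,
      scar_primary = stats::setNames(as.list(draws$scar_primary),
                                     c("loh", "tai", "lst")),
      scar_relapse = stats::setNames(as.list(draws$scar_relapse),
                                     c("loh", "tai", "lst")),
      wgd_relapse = draws$wgd,
      relapse_hrd = sim_tree$relapse_hrd ||
        sum(draws$scar_relapse) >= analysis_constants()$hrd_phenotype_threshold,
      burden_primary = draws$burden_p, burden_relapse = draws$burden_r,
      weights_primary = lesions$primary$weights,
      weights_relapse = lesions$relapse$weights,
      hr_scenario = scn$name, hr_gene = scn$gene,
      hr_expected_relapse = scn$expected_relapse)
  }
  mutations <- if (length(mutations)) do.call(rbind, c(mutations,
                                                       make.row.names = FALSE))
  else simulate_mutations(c(1, 0, 0), 0)
  hr_variants <- if (length(hr_rows)) do.call(rbind, c(hr_rows,
                                                       make.row.names = FALSE))
  else data.frame(sample = character(), lesion = character(),
                  gene = character(), event = character())
  bundle <- structure(list(profiles = profiles, trees = trees,
                           mutations = mutations, hr_variants = hr_variants,
                           truth = truth, params = params),
                      class = "CohortBundle")
  if (!is.null(out_dir)) write_cohort(bundle, out_dir)
  bundle
}

#' @export
print.CohortBundle <- function(x, ...) {
  cat("CohortBundle:", length(x$trees), "patients,",
      length(x$profiles), "profiles,", nrow(x$mutations), "mutations\n")
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' @param bundle a \code{CohortBundle}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_cohort <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  if (length(bundle$profiles))
    write_segments(bundle$profiles, file.path(out_dir, "segments.tsv"))
  write_mutations(bundle$mutations, file.path(out_dir, "mutations.tsv"))
  utils::write.table(bundle$hr_variants,
                     file.path(out_dir, "hr_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (pid in names(bundle$trees))
    write_tree(bundle$trees[[pid]],
               file.path(out_dir, "trees", paste0(pid, ".json")))
  json <- jsonlite::toJSON(bundle$truth, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(out_dir, "truth.json"))
  invisible(out_dir)
}
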