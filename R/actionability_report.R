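#' @title Actionability report, cohort summaries and paired statistics
#' @description Integrates scar, bi-allelic and clonal outputs into a
#'   per-lesion actionability report (HRD phenotype for PARP inhibitors /
#'   DNA crosslinking agents, plus OncoKB-style rule hits for FDA-approved
#'   drugs), summarizes clinical characteristics, and provides the paired
#'   nonparametric comparison and Pearson correlation used at cohort level.
#' @name actionability_report
NULL

#' Bundled actionability rule table
#'
#' Local stand-in for evidence levels 1-2 of a precision-oncology knowledge
#' base; covers the genes used by the bundled report fixture. Replace via
#' [read_rules()] for a fuller table.
#'
#' @return data.frame: gene, alteration, level.
#' @export
default_rules <- function() {
  read_rules(system.file("extdata", "oncokb_rules_synthetic.tsv",
                         package = "relapseEvo", mustWork = TRUE))
}

#' Flag actionable events for a set of lesions
#'
#' Produces one record per OncoKB-style rule hit and one per HRD-phenotype
#' lesion. Rule hits carry the clone, CCF and trunk/branch classification of
#' the alteration; HRD records carry \code{NA} for all three. Records are
#' ordered by patient, lesion (primary first), biomarker (rule hits before
#' HRD), clone, kind (mutation before amplification), gene.
#'
#' @param alterations data.frame with columns \code{sample}, \code{lesion},
#'   \code{gene}, \code{kind} (mutation/amplification), \code{clone} (node
#'   id, may be NA), \code{ccf} (may be NA) and optionally
#'   \code{classification} (trunk/branch; derived from \code{trees} when
#'   absent and a tree is available).
#' @param rules rule table from [read_rules()] / [default_rules()].
#' @param hrd_status data.frame with columns \code{sample}, \code{lesion},
#'   \code{hrd_phenotype} (logical) and optionally \code{hrd_reason}
#'   (description, e.g. \code{"(HRD score >= 42)"}).
#' @param trees optional named list of \code{TreeDocument}s keyed by sample
#'   id, used to derive trunk/branch labels from clone ids.
#' @param known_genes optional gene universe; rules outside it draw a
#'   warning (never an error).
#' @return data.frame of actionability records: sample, lesion, biomarker,
#'   alteration, clone, ccf, classification.
#' @export
flag_actionable <- function(alterations, rules, hrd_status, trees = NULL,
                            known_genes = NULL) {
  if (!is.null(known_genes)) {
    unknown <- setdiff(rules$gene, known_genes)
    if (length(unknown))
      warning("rule references unknown gene(s): ",
              paste(unknown, collapse = ", "))
  }
  empty <- data.frame(sample = character(), lesion = character(),
                      biomarker = character(), alteration = character(),
                      clone = character(), ccf = numeric(),
                      classification = character(), stringsAsFactors = FALSE)
  recs <- list()
  if (nrow(alterations)) {
    key <- paste(rules$gene, rules$alteration)
    for (i in seq_len(nrow(alterations))) {
      a <- alterations[i, ]
      if (!paste(a$gene, a$kind) %in% key) next
      cls <- if ("classification" %in% names(alterations) &&
                 !is.na(a$classification)) a$classification
      else if (!is.null(trees) && !is.na(a$clone) &&
               a$sample %in% names(trees))
        label_trunk_branch(trees[[a$sample]], node = as.character(a$clone))
      else NA_character_
      recs[[length(recs) + 1L]] <- data.frame(
        sample = a$sample, lesion = a$lesion, biomarker = "OncoKB",
        alteration = paste(a$gene, a$kind),
        clone = as.character(a$clone), ccf = a$ccf, classification = cls,
        kind = a$kind, gene = a$gene, stringsAsFactors = FALSE)
    }
  }
  if (nrow(hrd_status)) for (i in seq_len(nrow(hrd_status))) {
    h <- hrd_status[i, ]
    if (!isTRUE(h$hrd_phenotype)) next
    reason <- if ("hrd_reason" %in% names(hrd_status) && !is.na(h$hrd_reason))
      h$hrd_reason else "(HRD score >= 42)"
    recs[[length(recs) + 1L]] <- data.frame(
      sample = h$sample, lesion = h$lesion, biomarker = "HRD",
      alteration = reason, clone = NA_character_, ccf = NA_real_,
      classification = NA_character_, kind = "", gene = "",
      stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  ord <- order(out$sample,
               match(out$lesion, LESIONS),
               match(out$biomarker, c("OncoKB", "HRD")),
               out$clone,
               match(out$kind, c("mutation", "amplification")),
               out$gene)
  out <- out[ord, setdiff(names(out), c("kind", "gene")), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of lesions with at least one actionable event
#'
#' @param records data.frame from [flag_actionable()].
#' @param n_lesions total number of lesions in the cohort.
#' @return list: \code{n_hit} distinct lesions with a record,
#'   \code{fraction} in [0, 1].
#' @export
cohort_actionability_summary <- function(records, n_lesions) {
  stopifnot(n_lesions > 0)
  n_hit <- if (nrow(records))
    nrow(unique(records[c("sample", "lesion")])) else 0L
  list(n_hit = n_hit, fraction = n_hit / n_lesions)
}

#' Summarize clinical characteristics
#'
#' Age and relapse interval use only non-missing values. Grade fractions
#' are computed among graded patients; subtype fractions use all patients
#' as denominator (a missing subtype is an observed absence of a label, not
#' an excluded record). Fractions are percentages rounded to one decimal.
#'
#' @param clinical data.frame from [read_clinical()].
#' @return list: median_age, age_range, subtype_percent (named),
#'   grade2_percent (NA if no graded patient), relapse_months_range.
#' @export
summarize_clinical <- function(clinical) {
  age <- clinical$age[!is.na(clinical$age)]
  grade <- clinical$grade[!is.na(clinical$grade)]
  months <- clinical$relapse_months[!is.na(clinical$relapse_months)]
  subtypes <- unique(clinical$subtype[!is.na(clinical$subtype)])
  subtype_percent <- vapply(subtypes, function(s)
    round(100 * sum(!is.na(clinical$subtype) & clinical$subtype == s) /
            nrow(clinical), 1), numeric(1L))
  list(
    median_age = stats::median(age),
    age_range = range(age),
    subtype_percent = subtype_percent,
    grade2_percent = if (length(grade))
      round(100 * sum(grade == 2) / length(grade), 1) else NA_real_,
    relapse_months_range = if (length(months)) range(months)
    else c(NA_real_, NA_real_)
  )
}

# exact null distribution of the signed-rank statistic by enumerating all
# 2^n sign assignments over the (doubled, hence integer) ranks
signed_rank_exact_p <- function(ranks2, W2, alternative) {
  counts <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts)
    counts <- c(counts, rep(0, r)) + shifted
  }
  total <- sum(counts)
  sums <- seq_along(counts) - 1L
  p_ge <- sum(counts[sums >= W2]) / total
  p_le <- sum(counts[sums <= W2]) / total
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Paired one-tailed nonparametric comparison
#'
#' Wilcoxon signed-rank test on within-pair differences
#' \code{relapse - primary} (the standard paired nonparametric comparison;
#' a literal two-sample Mann-Whitney U would ignore the pairing). Zero
#' differences are dropped; with \code{alternative = "greater"} the test
#' asks whether relapse values are systematically higher. For 15 or fewer
#' nonzero pairs the null distribution is enumerated exactly over all sign
#' assignments (valid under ties via midranks); larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param primary,relapse equal-length paired numeric vectors (>= 3 pairs).
#' @param alternative "greater" (default), "less" or "two.sided".
#' @return list: statistic (signed-rank sum W+), p.value, n_effective,
#'   method.
#' @export
paired_comparison <- function(primary, relapse, alternative = "greater") {
  alternative <- match.arg(alternative, c("greater", "less", "two.sided"))
  stopifnot(length(primary) == length(relapse))
  if (length(primary) < 3L) stop("need at least 3 pairs")
  d <- relapse - primary
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all paired differences are zero; the test is undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 15L) {
    ranks2 <- as.integer(round(2 * r))
    p <- signed_rank_exact_p(ranks2, as.integer(round(2 * W)), alternative)
    method <- "exact signed-rank (enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    cc <- 0.5
    z <- switch(alternative,
                greater = (W - mu - cc) / sqrt(sigma2),
                less = (W - mu + cc) / sqrt(sigma2),
                two.sided = (W - mu - sign(W - mu) * cc) / sqrt(sigma2))
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "signed-rank, normal approximation"
  }
  list(statistic = W, p.value = p, n_effective = n, method = method)
}

#' Pearson correlation with p-value from the t transform
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return list: r, p.value, n.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p.value = p, n = n)
}
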