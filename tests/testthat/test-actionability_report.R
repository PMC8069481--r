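read_report_fixture <- function() {
  tab <- utils::read.delim(extdata("table2_actionability.tsv"),
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  tab$clone <- as.character(tab$clone)
  tab
}

test_that("the bundled report fixture closes through flag_actionable", {
  fixture <- read_report_fixture()
  expect_equal(nrow(fixture), 13L)
  onco <- fixture[fixture$biomarker == "OncoKB", ]
  alterations <- data.frame(
    sample = onco$sample, lesion = onco$lesion,
    gene = sub(" .*", "", onco$alteration),
    kind = sub(".* ", "", onco$alteration),
    clone = onco$clone, ccf = onco$ccf,
    classification = onco$classification, stringsAsFactors = FALSE)
  hrd <- fixture[fixture$biomarker == "HRD", ]
  hrd_status <- data.frame(sample = hrd$sample, lesion = hrd$lesion,
                           hrd_phenotype = TRUE, hrd_reason = hrd$alteration,
                           stringsAsFactors = FALSE)
  records <- flag_actionable(alterations, default_rules(), hrd_status)
  expect_equal(records, fixture[order(fixture$sample,
                                      match(fixture$lesion, c("primary", "relapse")),
                                      match(fixture$biomarker, c("OncoKB", "HRD")),
                                      fixture$clone), ],
               ignore_attr = TRUE)
  # regenerating from the same inputs is identical
  expect_identical(records,
                   flag_actionable(alterations, default_rules(), hrd_status))
  # cohort summary: 9 of 20 lesions carry at least one record
  summary <- cohort_actionability_summary(records, 20)
  expect_equal(summary$n_hit, 9L)
  expect_equal(summary$fraction, 0.45)
  # three HRD-phenotype relapse lesions, two PIK3CA lesions
  expect_equal(sum(records$biomarker == "HRD" &
                     records$lesion == "relapse"), 3L)
  expect_equal(sum(grepl("^PIK3CA", records$alteration)), 2L)
  # the BC03 BRCA2 branch mutation carries CCF 0.943
  bc03 <- records[records$sample == "BC03", ]
  expect_equal(bc03$ccf, 0.943)
  expect_equal(bc03$classification, "branch")
})

test_that("flag_actionable edge behavior", {
  empty_alt <- data.frame(sample = character(), lesion = character(),
                          gene = character(), kind = character(),
                          clone = character(), ccf = numeric())
  no_hrd <- data.frame(sample = "s", lesion = "primary",
                       hrd_phenotype = FALSE)
  expect_equal(nrow(flag_actionable(empty_alt, default_rules(), no_hrd)), 0L)
  # HRD lesion with no rule hits gives a single N/A record
  hrd1 <- data.frame(sample = "s", lesion = "relapse", hrd_phenotype = TRUE)
  rec <- flag_actionable(empty_alt, default_rules(), hrd1)
  expect_equal(nrow(rec), 1L)
  expect_true(is.na(rec$clone) && is.na(rec$ccf) && is.na(rec$classification))
  # alterations without a covering rule are dropped; unknown rule genes warn
  alt <- data.frame(sample = "s", lesion = "primary", gene = "KRAS",
                    kind = "mutation", clone = "2", ccf = 0.5)
  expect_equal(nrow(flag_actionable(alt, default_rules(), no_hrd)), 0L)
  expect_warning(
    flag_actionable(alt, default_rules(), no_hrd,
                    known_genes = c("KRAS", "TP53")),
    "unknown gene")
  # trunk/branch labels derived from a tree when not precomputed
  tr <- simulate_tree("SEEM", seed = 2, patient_id = "pt")$tree
  alt2 <- data.frame(sample = "pt_relapse", lesion = "relapse",
                     gene = "PIK3CA", kind = "mutation", clone = "1",
                     ccf = 1)
  rec2 <- flag_actionable(alt2, default_rules(),
                          data.frame(sample = character(),
                                     lesion = character(),
                                     hrd_phenotype = logical()),
                          trees = list(pt_relapse = tr))
  expect_equal(rec2$classification, "trunk")
})

test_that("clinical summary reproduces the cohort table statistics", {
  clin <- read_clinical(extdata("table1_clinical.tsv"))
  s <- summarize_clinical(clin)
  expect_equal(s$median_age, 47)
  expect_equal(s$age_range, c(27, 72))
  expect_equal(unname(s$subtype_percent["Luminal A-like"]), 50.0)
  expect_equal(s$grade2_percent, 77.8)
  expect_equal(s$relapse_months_range[2], 107)
  # all-missing grade column reports NA
  clin2 <- clin; clin2$grade <- NA
  expect_true(is.na(summarize_clinical(clin2)$grade2_percent))
})

test_that("paired comparison matches the enumeration oracle", {
  # uniform +1 shift over 10 pairs: exact one-sided p = 1/1024
  primary <- c(10, 12, 9, 14, 20, 7, 13, 16, 11, 8)
  relapse <- primary + 1
  res <- paired_comparison(primary, relapse)
  expect_equal(res$p.value, 1 / 1024)
  expect_equal(res$statistic, 55)
  # random paired data, including ties in |differences|
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- rpois(n, 20)
    y <- x + sample(c(-3, -1, 0, 1, 2, 3), n, replace = TRUE)
    if (all(y == x)) y[1] <- x[1] + 1
    expect_equal(paired_comparison(x, y)$p.value,
                 oracle_signed_rank_p(x, y), info = i)
  }
  # all-zero differences are an explicit error
  expect_error(paired_comparison(1:5, 1:5), "zero")
})

test_that("swapping the vectors reverses the one-sided tail", {
  set.seed(11)
  x <- rpois(8, 30); y <- x + sample(c(1, 2, 3, -1), 8, replace = TRUE)
  p_fwd <- paired_comparison(x, y, "greater")$p.value
  p_rev <- paired_comparison(y, x, "less")$p.value
  expect_equal(p_fwd, p_rev)
})

test_that("large-sample comparisons fall back to the normal approximation", {
  set.seed(3)
  x <- rnorm(40); y <- x + rnorm(40, 0.5)
  res <- paired_comparison(x, y)
  expect_match(res$method, "approximation")
  ref <- suppressWarnings(stats::wilcox.test(y, x, paired = TRUE,
                                             alternative = "greater",
                                             exact = FALSE, correct = TRUE))
  expect_equal(res$p.value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("correlate computes product-moment r with the t-transform p", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x)$r, 1)
  expect_equal(correlate(x, 2 * x)$p.value, 0)
  set.seed(5)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(correlate(a, b)$r), 0.1)
  # affine invariance
  expect_equal(correlate(a, b)$r, correlate(3 * a + 2, -1 * b)$r * -1)
  ref <- stats::cor.test(a, b)
  expect_equal(correlate(a, b)$p.value, unname(ref$p.value),
               tolerance = 1e-12)
})
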