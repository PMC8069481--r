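test_that("context labels are the canonical 96 in fixed order", {
  labels <- context_labels()
  expect_equal(length(labels), 96L)
  expect_equal(labels[1], "A[C>A]A")
  expect_equal(labels[96], "T[T>G]T")
  expect_false(anyDuplicated(labels) > 0)
})

test_that("purine-strand records collapse to the pyrimidine strand", {
  # G>A with 5' T and 3' C reported on the reference strand is C>T at G[C>T]A
  expect_equal(snv_context("G", "A", "T", "C"), "G[C>T]A")
  expect_equal(snv_context("C", "T", "G", "A"), "G[C>T]A")
  expect_equal(snv_context("A", "C", "A", "A"), "T[T>G]T")
  expect_error(snv_context("N", "A", "C", "C"), "non-ACGT")
})

test_that("build_catalog counts every record once and collapses strands", {
  muts <- simulate_mutations(c(0.4, 0.4, 0.2), 500, seed = 3,
                             sample_id = "s1")
  cat1 <- build_catalog(muts)
  expect_equal(sum(cat1), 500L)
  expect_equal(dim(cat1), c(1L, 96L))
  # strand-collapse involution: reverse-complementing all records changes
  # nothing
  rc <- muts
  rc$ref <- relapseEvo:::revcomp_base(muts$ref)
  rc$alt <- relapseEvo:::revcomp_base(muts$alt)
  rc$five_prime <- relapseEvo:::revcomp_base(muts$three_prime)
  rc$three_prime <- relapseEvo:::revcomp_base(muts$five_prime)
  expect_equal(build_catalog(rc), cat1)
  expect_equal(sum(build_catalog(muts[0, ], samples = "s1")), 0L)
})

test_that("cosine similarity has the expected geometry", {
  u <- runif(96)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(u, 5 * u), 1)
  v <- c(1, 0, 0, 1); w <- c(0, 1, 1, 0)
  expect_equal(cosine_similarity(v, w), 0)
  set.seed(1)
  for (i in 1:10) {
    a <- runif(96); b <- runif(96)
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_equal(cosine_similarity(a, b), cosine_similarity(2 * a, 7 * b))
  }
  expect_error(cosine_similarity(rep(0, 4), c(1, 1, 1, 1)), "zero vector")
})

test_that("noiseless rank-2 factorizations are recovered", {
  sigs <- reference_signatures()[, c("age_like", "apobec_like")]
  E <- matrix(c(3000, 500, 400, 2500, 1200, 1800), ncol = 2, byrow = TRUE)
  V <- t(sigs %*% t(E))
  colnames(V) <- context_labels(); rownames(V) <- paste0("s", 1:3)
  d <- nmf_extract(V, rank = 2, seed = 4, n_restarts = 10)
  mm <- match_catalog(d, sigs)
  expect_true(all(mm$similarity > 0.99))
  expect_setequal(mm$best_match, c("age_like", "apobec_like"))
  # reconstruction close to input
  recon <- d$exposures %*% t(d$signatures)
  expect_lt(max(abs(recon - V)) / max(V), 0.05)
})

test_that("nmf_extract validates input and is deterministic under a seed", {
  V <- matrix(5, nrow = 2, ncol = 96,
              dimnames = list(c("a", "b"), context_labels()))
  expect_error(nmf_extract(V, rank = 3), "rank")
  expect_error(nmf_extract(V * 0, rank = 1), "no mutations")
  d1 <- nmf_extract(nmf_cohort_catalog(2, burden = 800), 2, seed = 9,
                    n_restarts = 3)
  d2 <- nmf_extract(nmf_cohort_catalog(2, burden = 800), 2, seed = 9,
                    n_restarts = 3)
  expect_equal(d1$signatures, d2$signatures)
  expect_equal(d1$exposures, d2$exposures)
})

test_that("more restarts never worsen the reconstruction error", {
  cat0 <- nmf_cohort_catalog(5, burden = 600)
  errs <- vapply(c(1, 3, 6), function(nr)
    nmf_extract(cat0, 2, seed = 3, n_restarts = nr)$reconstruction_error,
    numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("match_catalog flags weak matches below the 0.70 threshold", {
  sigs <- reference_signatures()
  d <- nmf_extract(nmf_cohort_catalog(3, burden = 1500), rank = 3,
                   seed = 1, n_restarts = 10)
  mm <- match_catalog(d, sigs)
  expect_true(all(mm$matched))
  # a reference catalog of spiky strangers should not match a flat-ish query
  spiky <- matrix(0, 96, 2, dimnames = list(context_labels(), c("x", "y")))
  spiky[1, 1] <- 1; spiky[50, 2] <- 1
  flatq <- nmf_extract(matrix(100, 1, 96,
                              dimnames = list("s", context_labels())),
                       rank = 1, seed = 1, n_restarts = 2)
  mm2 <- match_catalog(flatq, spiky)
  expect_false(any(mm2$matched))
  expect_error(match_catalog(d, matrix(numeric(0), 96, 0)), "empty")
})

test_that("exposure fractions normalize per sample and pool per group", {
  d <- nmf_extract(nmf_cohort_catalog(4, burden = 1000), rank = 3,
                   seed = 2, n_restarts = 5)
  fr <- exposure_fractions(d)
  expect_equal(unname(rowSums(fr$per_sample)), rep(1, nrow(fr$per_sample)))
  groups <- stats::setNames(rep(c("primary", "relapse"), length.out = 20),
                            rownames(d$exposures))
  fg <- exposure_fractions(d, groups)$per_group
  expect_equal(unname(rowSums(fg)), c(1, 1))
  # fractions invariant under joint exposure rescaling
  d2 <- d; d2$exposures <- d$exposures * 3
  expect_equal(exposure_fractions(d2)$per_sample, fr$per_sample)
})

test_that("BH q-values reproduce the hand-computed step-up", {
  # p = (0.01, 0.02, 0.03, 0.04), m = 4: q = (0.04, 0.04, 0.04, 0.04)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  exposures <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
                      dimnames = list(paste0("s", 1:6), "sig"))
  genes <- matrix(c(0, 0, 0, 1, 1, 1, 1, 0, 1, 0, 1, 0), ncol = 2,
                  dimnames = list(paste0("s", 1:6), c("gA", "gB")))
  scr <- signature_gene_screen(exposures, genes)
  expect_equal(nrow(scr), 2L)
  expect_true(all(scr$q >= scr$p))
  # constant indicator is skipped with a message
  genes2 <- cbind(genes, gC = rep(1, 6))
  expect_message(scr2 <- signature_gene_screen(exposures, genes2),
                 "constant indicator")
  expect_equal(nrow(scr2), 2L)
})

test_that("planted association ranks first in the screen", {
  set.seed(42)
  n <- 24
  gene_ind <- matrix(rbinom(n * 5, 1, 0.4), n, 5,
                     dimnames = list(paste0("s", 1:n), paste0("g", 1:5)))
  exposures <- matrix(rnorm(n * 2, 100, 5), n, 2,
                      dimnames = list(paste0("s", 1:n), c("sigA", "sigB")))
  exposures[, "sigA"] <- exposures[, "sigA"] + 60 * gene_ind[, "g3"]
  scr <- signature_gene_screen(exposures, gene_ind)
  top <- scr[which.min(scr$q), ]
  expect_equal(top$signature, "sigA")
  expect_equal(top$gene, "g3")
})
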