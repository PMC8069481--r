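#' @title Mutational signature extraction and matching
#' @description Builds the samples x 96 trinucleotide-context count matrix
#'   from mutation records (pyrimidine strand collapse), extracts de novo
#'   signatures by non-negative matrix factorization (NMF) with
#'   multiplicative updates minimizing generalized Kullback-Leibler
#'   divergence, matches extracted signatures to a reference catalog by
#'   cosine similarity, summarizes per-sample exposure fractions, and runs
#'   the signature-gene ordinary-least-squares screen with
#'   Benjamini-Hochberg correction.
#' @name mutational_signatures
NULL

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Canonical 96 trinucleotide context labels
#'
#' Fixed lexicographic order: substitution class (C>A, C>G, C>T, T>A, T>C,
#' T>G), then 5' base, then 3' base; labels look like \code{"A[C>T]G"}.
#' Every 96-vector in the package uses this order.
#'
#' @return character vector of length 96.
#' @export
context_labels <- function() {
  unlist(lapply(SUBSTITUTIONS, function(sub)
    unlist(lapply(BASES, function(p5)
      paste0(p5, "[", sub, "]", BASES)))))
}

revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Assign one SNV to its 96-context bin
#'
#' Records whose reference base is a purine are reverse-complemented to the
#' pyrimidine strand (ref, alt and both flanking bases) before binning.
#'
#' @param ref,alt single reference/alternate bases.
#' @param five_prime,three_prime flanking bases on the reported strand.
#' @return context label, e.g. \code{"T[C>T]A"}.
#' @export
snv_context <- function(ref, alt, five_prime, three_prime) {
  bases <- c(ref, alt, five_prime, three_prime)
  if (!all(bases %in% BASES))
    stop("non-ACGT base in mutation record: ",
         paste(bases[!bases %in% BASES], collapse = ", "))
  if (ref == alt) stop("ref and alt are identical")
  if (ref %in% c("A", "G")) {
    new5 <- revcomp_base(three_prime)
    three_prime <- revcomp_base(five_prime)
    five_prime <- new5
    ref <- revcomp_base(ref)
    alt <- revcomp_base(alt)
  }
  paste0(five_prime, "[", ref, ">", alt, "]", three_prime)
}

#' Build the samples x 96 mutation catalog
#'
#' @param mutations mutation data.frame as from [read_mutations()]. All rows
#'   are treated as single-nucleotide substitutions.
#' @param samples optional character vector fixing row order (defaults to
#'   order of first appearance).
#' @return integer matrix, samples x 96, with canonical context columns.
#' @export
build_catalog <- function(mutations, samples = NULL) {
  labels <- context_labels()
  if (is.null(samples)) samples <- unique(mutations$sample)
  mat <- matrix(0L, nrow = length(samples), ncol = 96L,
                dimnames = list(samples, labels))
  if (nrow(mutations)) {
    ctx <- vapply(seq_len(nrow(mutations)), function(i)
      snv_context(mutations$ref[i], mutations$alt[i],
                  mutations$five_prime[i], mutations$three_prime[i]),
      character(1L))
    tab <- table(factor(mutations$sample, levels = samples),
                 factor(ctx, levels = labels))
    mat[] <- as.integer(tab)
  }
  mat
}

#' Bundled synthetic reference signatures
#'
#' Three constructed 96-vectors used as the default reference catalog and by
#' the synthetic cohort generator:
#' \describe{
#'   \item{age_like}{90\% of mass on C>T at NpCpG contexts (clock-like,
#'     deamination of methylated CpG).}
#'   \item{apobec_like}{94\% of mass on C>T and C>G at TpC contexts
#'     (APOBEC cytosine deaminase activity).}
#'   \item{flat}{uniform over all 96 contexts.}
#' }
#' The vectors are constructed, not copied from any published catalog;
#' pairwise cosine similarities are below 0.3 so NMF recovery is well-posed.
#'
#' @return 96 x 3 matrix with canonical context rownames.
#' @export
reference_signatures <- function() {
  labels <- context_labels()
  sig <- function(main) {
    v <- stats::setNames(rep(0, 96L), labels)
    v[names(main)] <- main
    rest <- setdiff(labels, names(main))
    v[rest] <- (1 - sum(main)) / length(rest)
    v
  }
  age <- sig(c("A[C>T]G" = 0.225, "C[C>T]G" = 0.225,
               "G[C>T]G" = 0.225, "T[C>T]G" = 0.225))
  apobec <- sig(c("T[C>T]A" = 0.26, "T[C>T]T" = 0.26,
                  "T[C>G]A" = 0.21, "T[C>G]T" = 0.21))
  flat <- rep(1 / 96, 96L)
  mat <- cbind(age_like = age, apobec_like = apobec, flat = flat)
  rownames(mat) <- labels
  mat
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# generalized Kullback-Leibler divergence D(V || WH)
kl_divergence <- function(V, WH) {
  eps <- .Machine$double.eps
  pos <- V > 0
  sum(V[pos] * log(V[pos] / pmax(WH[pos], eps))) - sum(V) + sum(WH)
}

nmf_kl_run <- function(V, rank, max_iter, tol) {
  # V: 96 x n; multiplicative updates (Brunet)
  eps <- .Machine$double.eps
  m <- nrow(V); n <- ncol(V)
  W <- matrix(stats::runif(m * rank, 0.1, 1), m, rank)
  H <- matrix(stats::runif(rank * n, 0.1, 1), rank, n)
  prev <- Inf
  for (iter in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H)) / pmax(rep(rowSums(H), each = m), eps)
    if (iter %% 10L == 0L) {
      d <- kl_divergence(V, pmax(W %*% H, eps))
      if (is.finite(prev) && abs(prev - d) < tol * max(1, abs(prev))) break
      prev <- d
    }
  }
  list(W = W, H = H, div = kl_divergence(V, pmax(W %*% H, eps)))
}

#' Extract de novo signatures by NMF
#'
#' Factorizes the catalog (transposed to 96 x samples) as \code{W H} with
#' multiplicative updates minimizing generalized KL divergence, keeping the
#' best of \code{n_restarts} seeded initializations. Signature columns are
#' rescaled to sum to 1, with exposures absorbing the magnitude, so each
#' sample's exposures sum to its mutation count in the reconstruction.
#'
#' @param catalog samples x 96 count matrix from [build_catalog()].
#' @param rank number of signatures to extract (>= 1, <= number of samples).
#' @param seed integer seed; the i-th restart uses \code{seed + i}.
#' @param n_restarts number of random restarts (default 30).
#' @param max_iter maximum update iterations per restart.
#' @param tol relative KL convergence tolerance.
#' @return list of class \code{SignatureDecomposition}: \code{signatures}
#'   (96 x rank, columns sum to 1), \code{exposures} (samples x rank),
#'   \code{reconstruction_error} (generalized KL), \code{rank}, \code{seed}.
#' @export
nmf_extract <- function(catalog, rank, seed = 1L, n_restarts = 30L,
                        max_iter = 2000L, tol = 1e-6) {
  stopifnot(is.matrix(catalog), ncol(catalog) == 96L)
  if (rank < 1L || rank > min(nrow(catalog), 96L))
    stop("rank must lie in [1, min(samples, 96)]")
  if (sum(catalog) <= 0) stop("catalog has no mutations")
  V <- t(catalog)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r, nmf_kl_run(V, rank, max_iter, tol))
    if (is.null(best) || fit$div < best$div) best <- fit
  }
  scale <- colSums(best$W)
  W <- sweep(best$W, 2L, scale, "/")
  H <- sweep(best$H, 1L, scale, "*")
  colnames(W) <- paste0("denovo_", seq_len(rank))
  rownames(W) <- colnames(catalog)
  exposures <- t(H)
  dimnames(exposures) <- list(rownames(catalog), colnames(W))
  structure(list(signatures = W, exposures = exposures,
                 reconstruction_error = best$div, rank = rank, seed = seed),
            class = "SignatureDecomposition")
}

#' @export
print.SignatureDecomposition <- function(x, ...) {
  cat("SignatureDecomposition: rank", x$rank, "over",
      nrow(x$exposures), "samples; KL error",
      format(x$reconstruction_error, digits = 4), "\n")
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' @param u,v equal-length numeric vectors.
#' @return \code{u.v / (|u||v|)}; 1 for parallel, 0 for orthogonal vectors.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

#' Match de novo signatures to a reference catalog
#'
#' Greedy per-signature argmax: each extracted signature is paired with its
#' most cosine-similar reference (ties broken by reference order) and
#' flagged matched when similarity exceeds \code{cosine_match_threshold}.
#'
#' @param decomp a \code{SignatureDecomposition}.
#' @param reference 96 x k reference matrix (e.g. [reference_signatures()]).
#' @param constants [analysis_constants()] list.
#' @return data.frame: signature, best_match, similarity, matched.
#' @export
match_catalog <- function(decomp, reference,
                          constants = analysis_constants()) {
  stopifnot(inherits(decomp, "SignatureDecomposition"))
  if (is.null(dim(reference)) || ncol(reference) < 1L)
    stop("reference catalog is empty")
  stopifnot(nrow(reference) == 96L)
  rows <- lapply(colnames(decomp$signatures), function(sig) {
    sims <- apply(reference, 2L, cosine_similarity,
                  v = decomp$signatures[, sig])
    best <- which.max(sims)  # first maximum: ties broken by reference order
    data.frame(signature = sig,
               best_match = colnames(reference)[best],
               similarity = unname(sims[best]),
               matched = unname(sims[best]) > constants$cosine_match_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-sample and per-group signature exposure fractions
#'
#' Per-sample fractions normalize each sample's exposures to sum to 1.
#' Group summaries are exposure-weighted: exposures are summed over the
#' group's samples and then normalized, so samples contribute in proportion
#' to their mutation counts.
#'
#' @param decomp a \code{SignatureDecomposition}.
#' @param groups optional named character vector mapping sample id to group
#'   label.
#' @return list with \code{per_sample} (samples x rank fractions) and, when
#'   \code{groups} is given, \code{per_group} (groups x rank fractions).
#' @export
exposure_fractions <- function(decomp, groups = NULL) {
  E <- decomp$exposures
  totals <- rowSums(E)
  if (any(totals <= 0)) stop("sample with zero total exposure")
  out <- list(per_sample = sweep(E, 1L, totals, "/"))
  if (!is.null(groups)) {
    missing <- setdiff(rownames(E), names(groups))
    if (length(missing))
      stop("no group for sample(s): ", paste(missing, collapse = ", "))
    g <- groups[rownames(E)]
    sums <- rowsum(E, g)
    out$per_group <- sweep(sums, 1L, rowSums(sums), "/")
  }
  out
}

#' Signature-gene regression screen
#'
#' For each (signature, gene) pair, ordinary least squares of the signature
#' exposure on the per-sample gene mutation indicator; Benjamini-Hochberg
#' step-up over all tested pairs. Pairs with a constant exposure or
#' indicator are skipped with a message.
#'
#' @param exposures samples x k exposure matrix.
#' @param gene_indicators samples x genes 0/1 matrix (same row order).
#' @return data.frame: signature, gene, slope, p, q (BH-adjusted).
#' @export
signature_gene_screen <- function(exposures, gene_indicators) {
  stopifnot(nrow(exposures) == nrow(gene_indicators))
  if (nrow(exposures) < 3L) stop("need at least 3 samples")
  rows <- list()
  for (sig in colnames(exposures)) {
    y <- exposures[, sig]
    if (stats::sd(y) == 0) {
      message("skipping constant exposure vector: ", sig)
      next
    }
    for (gene in colnames(gene_indicators)) {
      x <- gene_indicators[, gene]
      if (stats::sd(x) == 0) {
        message("skipping constant indicator: ", gene)
        next
      }
      fit <- stats::lm(y ~ x)
      coefs <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        signature = sig, gene = gene,
        slope = coefs["x", "Estimate"],
        p = coefs["x", "Pr(>|t|)"],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(signature = character(), gene = character(),
                      slope = numeric(), p = numeric(), q = numeric()))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
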