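#' @title Clone-tree algebra: abundance, diversity and evolution models
#' @description Operations on consumed clone trees: per-sample clonal
#'   abundances from inclusive cancer cell fractions (CCFs), Shannon and
#'   Gini-Simpson diversity, trunk/branch labeling of alterations,
#'   surviving-subclone detection and the three-way evolution-model
#'   classification (DNSEM / HRDEM / SEEM).
#'
#'   Node CCFs are inclusive: a node's CCF includes all of its descendants,
#'   so a clone's own abundance is its CCF minus the total CCF of its
#'   children, floored at zero.
#' @name clonal_architecture
NULL

#' Clonal abundance of a sample
#'
#' For every clone except the normal (root) clone, the abundance is
#' \code{max(0, ccf - sum(children ccf))}; clones with positive abundance
#' are retained and renormalized to sum to 1.
#'
#' @param tree a \code{TreeDocument}.
#' @param sample sample label present in the tree.
#' @return list of class \code{CloneAbundance}: \code{sample},
#'   \code{clone_ids}, \code{p} (abundances summing to 1), \code{n}
#'   (number of retained clones).
#' @export
clonal_abundance <- function(tree, sample) {
  stopifnot(inherits(tree, "TreeDocument"))
  if (!sample %in% tree$samples) stop("unknown sample label: ", sample)
  root <- tree_root(tree)
  ids <- setdiff(tree$nodes$id, root)
  raw <- vapply(ids, function(id) {
    kids <- tree_children(tree, id)
    ccf <- node_ccf(tree, id, sample)
    kid_ccf <- if (length(kids)) sum(node_ccf(tree, kids, sample)) else 0
    max(0, ccf - kid_ccf)
  }, numeric(1L))
  keep <- raw > 0
  if (!any(keep)) stop("all clonal abundances are zero in sample ", sample)
  p <- raw[keep] / sum(raw[keep])
  structure(list(sample = sample, clone_ids = ids[keep],
                 p = unname(p), n = sum(keep)),
            class = "CloneAbundance")
}

#' Shannon diversity index
#'
#' \code{H = -sum(p_i * log(p_i))} over clone abundances; zero-abundance
#' terms contribute 0.
#'
#' @param ab a \code{CloneAbundance} or a bare abundance vector summing
#'   to 1.
#' @return H >= 0 (natural log).
#' @export
shannon_index <- function(ab) {
  p <- abundance_vector(ab)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gini-Simpson diversity index
#'
#' \code{D = 1 - sum(p_i^2)}: the probability that two random tumor cells
#' come from distinct clones.
#'
#' @inheritParams shannon_index
#' @return D in [0, 1).
#' @export
gini_simpson <- function(ab) {
  p <- abundance_vector(ab)
  1 - sum(p^2)
}

abundance_vector <- function(ab) {
  p <- if (inherits(ab, "CloneAbundance")) ab$p else as.numeric(ab)
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("abundances must sum to 1")
  p
}

#' Trunk / branch label of an alteration
#'
#' Alterations assigned to the founder clone (the root's only child) are
#' trunk; alterations in any descendant of the founder are branch.
#' Assignment to the root (normal clone) is an error.
#'
#' @param tree a \code{TreeDocument}.
#' @param alteration alteration id present in \code{tree$assignments}, or a
#'   node id via \code{node}.
#' @param node optional node id, bypassing the assignment lookup.
#' @return \code{"trunk"} or \code{"branch"}.
#' @export
label_trunk_branch <- function(tree, alteration = NULL, node = NULL) {
  stopifnot(inherits(tree, "TreeDocument"))
  if (is.null(node)) {
    if (is.null(alteration)) stop("give an alteration id or a node id")
    if (!alteration %in% names(tree$assignments))
      stop("unknown alteration: ", alteration)
    node <- tree$assignments[[alteration]]
  }
  if (!node %in% tree$nodes$id) stop("unknown node: ", node)
  if (node == tree_root(tree))
    stop("alteration assigned to the normal (root) clone")
  if (node == tree_founder(tree)) "trunk" else "branch"
}

#' Subclones of the primary tumor that survived treatment
#'
#' Nodes other than the root and the founder with primary CCF above
#' \code{surviving_min_ccf} and relapse CCF above \code{surviving_min_ccf}.
#' The reported CCF is the node's inclusive relapse CCF (it contains the
#' node's descendants).
#'
#' @param tree a \code{TreeDocument} with \code{primary} and \code{relapse}
#'   samples.
#' @param constants [analysis_constants()] list.
#' @return data.frame: \code{node}, \code{primary_ccf}, \code{relapse_ccf}
#'   (possibly empty).
#' @export
surviving_subclones <- function(tree, constants = analysis_constants()) {
  stopifnot(inherits(tree, "TreeDocument"))
  for (s in c("primary", "relapse"))
    if (!s %in% tree$samples) stop("tree lacks sample label: ", s)
  excl <- c(tree_root(tree), tree_founder(tree))
  ids <- setdiff(tree$nodes$id, excl)
  pr <- node_ccf(tree, ids, "primary")
  re <- node_ccf(tree, ids, "relapse")
  keep <- pr > constants$surviving_min_ccf & re > constants$surviving_min_ccf
  data.frame(node = ids[keep], primary_ccf = pr[keep],
             relapse_ccf = re[keep], stringsAsFactors = FALSE)
}

#' Classify the evolution model of a patient's lesion pair
#'
#' Rule order, total over all inputs:
#' \enumerate{
#'   \item SEEM (selective expansion): some surviving primary subclone has
#'     inclusive relapse CCF > \code{seem_dominant_ccf} (dominant, child
#'     clones included).
#'   \item HRDEM (HRD-driven relapse): a surviving subclone exists with
#'     inclusive relapse CCF < \code{minor_surviving_ccf} and the relapse
#'     lesion has the HRD phenotype.
#'   \item DNSEM (de novo subclone emergence): no primary subclone survived;
#'     relapse derives solely from the founder clone.
#'   \item otherwise \code{unclassified}, with the evidence retained.
#' }
#'
#' @param tree a \code{TreeDocument}.
#' @param relapse_hrd logical, HRD phenotype of the relapse lesion.
#' @param constants [analysis_constants()] list.
#' @return list of class \code{EvolutionCall}: \code{patient_id},
#'   \code{model}, \code{evidence} (surviving-subclone table plus
#'   \code{relapse_hrd}).
#' @export
classify_evolution_model <- function(tree, relapse_hrd,
                                     constants = analysis_constants()) {
  surv <- surviving_subclones(tree, constants)
  model <-
    if (nrow(surv) && any(surv$relapse_ccf > constants$seem_dominant_ccf)) {
      "SEEM"
    } else if (nrow(surv) &&
               any(surv$relapse_ccf < constants$minor_surviving_ccf) &&
               isTRUE(relapse_hrd)) {
      "HRDEM"
    } else if (!nrow(surv)) {
      "DNSEM"
    } else {
      "unclassified"
    }
  structure(list(patient_id = tree$patient_id, model = model,
                 evidence = list(surviving = surv,
                                 relapse_hrd = isTRUE(relapse_hrd))),
            class = "EvolutionCall")
}

#' @export
print.EvolutionCall <- function(x, ...) {
  cat("EvolutionCall", x$patient_id, "->", x$model, "(",
      nrow(x$evidence$surviving), "surviving subclones )\n")
  invisible(x)
}

#' Primary-to-relapse diversity comparison
#'
#' Computes Shannon and Gini-Simpson indices for both lesions of each tree.
#' A patient is flagged \code{elevated} only when both indices strictly
#' increase from primary to relapse; discordant index directions set
#' \code{discordant} instead.
#'
#' @param trees list of \code{TreeDocument}s.
#' @return data.frame: patient, H_primary, H_relapse, D_primary, D_relapse,
#'   elevated, discordant.
#' @export
diversity_comparison <- function(trees) {
  rows <- lapply(trees, function(tree) {
    hp <- shannon_index(clonal_abundance(tree, "primary"))
    hr <- shannon_index(clonal_abundance(tree, "relapse"))
    dp <- gini_simpson(clonal_abundance(tree, "primary"))
    dr <- gini_simpson(clonal_abundance(tree, "relapse"))
    up_h <- hr > hp
    up_d <- dr > dp
    data.frame(patient = tree$patient_id,
               H_primary = hp, H_relapse = hr,
               D_primary = dp, D_relapse = dr,
               elevated = up_h && up_d,
               discordant = xor(up_h, up_d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
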