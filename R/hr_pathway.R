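#' @title Bi-allelic HR-gene alteration classification
#' @description Classifies, per lesion and gene, whether both alleles of a
#'   homologous-recombination (HR) gene are lost. Bi-allelic
#'   loss-of-function (LOF) mechanisms, in priority order:
#'   (1) germline LOF + somatic LOH of the wild-type allele,
#'   (2) germline LOF + somatic LOF in the same gene,
#'   (3) somatic LOF + somatic LOH,
#'   (4) two somatic LOF mutations in the same gene,
#'   (5) somatic deep deletion.
#'   Bi-allelic variant-of-uncertain-significance (VUS) mechanisms:
#'   (6) germline LOF + somatic VUS, (7) somatic LOF + somatic VUS,
#'   (8) somatic VUS + somatic LOH. Bi-allelic VUS in HR-deficient lesions
#'   with no other bi-allelic LOF gene are upgraded to putative LOF.
#' @name hr_pathway
NULL

HR_STATUS_LEVELS <- c("biallelic_lof", "biallelic_vus", "monoallelic", "none")

HR_MECHANISMS <- c(
  "germline_lof+somatic_loh",   # 1
  "germline_lof+somatic_lof",   # 2
  "somatic_lof+somatic_loh",    # 3
  "two_somatic_lof",            # 4
  "deep_deletion",              # 5
  "germline_lof+somatic_vus",   # 6
  "somatic_lof+somatic_vus",    # 7
  "somatic_vus+somatic_loh"     # 8
)

#' Bundled HR gene list
#'
#' 102 core and related HR-pathway gene symbols shipped as an editable
#' fixture (a constructed stand-in for published HR gene lists; replace via
#' \code{path} to use your own).
#'
#' @param path optional path to a one-symbol-per-line file.
#' @return character vector of gene symbols.
#' @export
hr_gene_list <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hr_genes_synthetic.txt",
                        package = "relapseEvo", mustWork = TRUE)
  genes <- readLines(path)
  genes <- trimws(genes[nzchar(trimws(genes))])
  if (anyDuplicated(genes)) stop("duplicate genes in HR list")
  genes
}

# per-gene event counts from a long event table for one sample/lesion
hr_event_counts <- function(events, gene) {
  rows <- events[events$gene == gene, , drop = FALSE]
  counts <- table(factor(rows$event, levels = HR_EVENT_TYPES))
  as.list(counts)
}

#' Classify the allelic status of one HR gene in one lesion
#'
#' Resolves the event combination to the highest-priority status
#' (biallelic_lof > biallelic_vus > monoallelic > none) and records which
#' numbered mechanism fired. A lone germline VUS never contributes; two
#' germline LOF mutations without somatic events are classified monoallelic
#' (compound germline inheritance cannot be established) and flagged.
#'
#' @param events long-format event data.frame for one sample/lesion, as from
#'   [read_hr_variants()] (columns \code{gene}, \code{event}).
#' @param gene gene symbol; must be on the HR list.
#' @param hr_genes character vector of allowed genes.
#' @return list of class \code{GeneAllelicStatus}: \code{gene},
#'   \code{status}, \code{mechanism} (index into the 8 combinations or
#'   \code{NA}), \code{mechanism_label}, \code{germline_involved},
#'   \code{compound_germline}.
#' @export
classify_gene <- function(events, gene, hr_genes = hr_gene_list()) {
  if (!gene %in% hr_genes) stop("gene not on the HR list: ", gene)
  n <- hr_event_counts(events, gene)
  mech <- NA_integer_
  if (n$germline_lof >= 1 && n$somatic_loh >= 1) mech <- 1L
  else if (n$germline_lof >= 1 && n$somatic_lof >= 1) mech <- 2L
  else if (n$somatic_lof >= 1 && n$somatic_loh >= 1) mech <- 3L
  else if (n$somatic_lof >= 2) mech <- 4L
  else if (n$deep_deletion >= 1) mech <- 5L
  else if (n$germline_lof >= 1 && n$somatic_vus >= 1) mech <- 6L
  else if (n$somatic_lof >= 1 && n$somatic_vus >= 1) mech <- 7L
  else if (n$somatic_vus >= 1 && n$somatic_loh >= 1) mech <- 8L
  status <- if (!is.na(mech) && mech <= 5L) "biallelic_lof"
    else if (!is.na(mech)) "biallelic_vus"
    else if (n$germline_lof >= 1 || n$somatic_lof >= 1 || n$somatic_vus >= 1)
      "monoallelic"
    else "none"
  structure(list(
    gene = gene, status = status, mechanism = mech,
    mechanism_label = if (is.na(mech)) NA_character_ else HR_MECHANISMS[mech],
    germline_involved = n$germline_lof >= 1 || n$germline_vus >= 1,
    compound_germline = n$germline_lof >= 2 && is.na(mech)
  ), class = "GeneAllelicStatus")
}

#' Classify every altered HR gene of one lesion
#'
#' @param events long-format event data.frame for one sample/lesion.
#' @param hr_genes character vector of allowed genes.
#' @return data.frame status map: gene, status, mechanism, mechanism_label,
#'   germline_involved, compound_germline, putative_lof (FALSE until
#'   [upgrade_putative_lof()]).
#' @export
classify_lesion <- function(events, hr_genes = hr_gene_list()) {
  genes <- sort(unique(events$gene))
  off_list <- setdiff(genes, hr_genes)
  if (length(off_list))
    stop("gene not on the HR list: ", paste(off_list, collapse = ", "))
  rows <- lapply(genes, function(g) {
    st <- classify_gene(events, g, hr_genes)
    data.frame(gene = st$gene, status = st$status,
               mechanism = st$mechanism,
               mechanism_label = st$mechanism_label,
               germline_involved = st$germline_involved,
               compound_germline = st$compound_germline,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene = character(), status = character(),
                  mechanism = integer(), mechanism_label = character(),
                  germline_involved = logical(),
                  compound_germline = logical())
  out$putative_lof <- logical(nrow(out))
  out
}

#' Upgrade bi-allelic VUS to putative LOF in HR-deficient lesions
#'
#' Bi-allelic VUS genes gain the \code{putative_lof} annotation iff the
#' lesion has the HRD phenotype and no gene in the map is bi-allelic LOF.
#'
#' @param status_map data.frame from [classify_lesion()].
#' @param hrd_phenotype logical HRD phenotype of the lesion.
#' @return the status map with \code{putative_lof} updated.
#' @export
upgrade_putative_lof <- function(status_map, hrd_phenotype) {
  status_map$putative_lof <- logical(nrow(status_map))
  if (isTRUE(hrd_phenotype) &&
      !any(status_map$status == "biallelic_lof")) {
    status_map$putative_lof <- status_map$status == "biallelic_vus"
  }
  status_map
}

biallelic_genes <- function(status_map) {
  status_map$gene[status_map$status == "biallelic_lof" |
                    status_map$putative_lof]
}

#' Bi-allelic events shared by both lesions of a patient
#'
#' A gene is shared when it is bi-allelic (LOF, or VUS upgraded to putative
#' LOF) in both the primary and the relapse status maps.
#'
#' @param primary_map,relapse_map status maps from [classify_lesion()]
#'   (after [upgrade_putative_lof()] if upgrades should count).
#' @return data.frame: gene, shared (TRUE rows only genes bi-allelic in at
#'   least one lesion).
#' @export
shared_events <- function(primary_map, relapse_map) {
  bp <- biallelic_genes(primary_map)
  br <- biallelic_genes(relapse_map)
  genes <- sort(union(bp, br))
  data.frame(gene = genes, shared = genes %in% intersect(bp, br),
             stringsAsFactors = FALSE)
}
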