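#' @title Readers and writers for on-disk artifacts
#' @description SEG-like segment tables, MAF-lite mutation tables, clone-tree
#'   JSON, signature catalogs, actionability rule tables and HR-variant
#'   tables. All writers emit byte-stable output for a fixed input so golden
#'   file tests are meaningful.
#' @name io_formats
NULL

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                     "start_stop", "silent", "other")
LOF_CLASSES <- c("nonsense", "frameshift", "splice", "start_stop")
VUS_CLASSES <- "missense"
LESIONS <- c("primary", "relapse")
HR_EVENT_TYPES <- c("germline_lof", "germline_vus", "somatic_lof",
                    "somatic_vus", "somatic_loh", "deep_deletion")

# child CCF may exceed its parent by this much before a tree is rejected;
# absorbs sampling noise in upstream tree inference
CCF_MONOTONE_TOL <- 0.02

#' Construct and validate a segment profile
#'
#' A segment profile is one sample's allele-specific copy-number profile:
#' sorted, non-overlapping segments with integer major/minor copy numbers,
#' plus tumor purity and ploidy.
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{major_cn}, \code{minor_cn}, \code{cell_frac}.
#' @param lesion \code{"primary"}, \code{"relapse"} or \code{NA}.
#' @param purity tumor purity in (0, 1].
#' @param ploidy average tumor ploidy, > 0.
#' @return An object of class \code{SegmentProfile}.
#' @export
segment_profile <- function(sample_id, segments, lesion = NA_character_,
                            purity = 1, ploidy = 2) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!is.na(lesion) && !lesion %in% LESIONS)
    stop("lesion must be one of: ", paste(LESIONS, collapse = ", "))
  if (!is.numeric(purity) || purity <= 0 || purity > 1)
    stop("purity must lie in (0, 1]")
  if (!is.numeric(ploidy) || ploidy <= 0) stop("ploidy must be positive")
  segments <- validate_segments(segments, sample_id)
  structure(list(sample_id = sample_id, lesion = lesion,
                 purity = purity, ploidy = ploidy, segments = segments),
            class = "SegmentProfile")
}

validate_segments <- function(seg, sample_id = "?") {
  required <- c("chrom", "start", "end", "major_cn", "minor_cn", "cell_frac")
  missing <- setdiff(required, names(seg))
  if (length(missing))
    stop("segment table missing column(s): ", paste(missing, collapse = ", "))
  seg <- seg[required]
  seg$chrom <- as.character(seg$chrom)
  for (col in c("start", "end", "major_cn", "minor_cn", "cell_frac"))
    seg[[col]] <- as.numeric(seg[[col]])
  if (nrow(seg)) {
    for (i in seq_len(nrow(seg))) {
      r <- seg[i, ]
      bad <- function(msg)
        stop("sample ", sample_id, ", segment row ", i, ": ", msg)
      if (anyNA(r)) bad("missing value")
      if (r$end < r$start) bad("end < start")
      if (r$major_cn < 0 || r$minor_cn < 0) bad("negative copy number")
      if (r$major_cn != round(r$major_cn) || r$minor_cn != round(r$minor_cn))
        bad("copy numbers must be integers")
      if (r$major_cn < r$minor_cn) bad("major_cn < minor_cn")
      if (r$cell_frac <= 0 || r$cell_frac > 1) bad("cell_frac outside (0, 1]")
    }
    seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
    for (chrom in unique(seg$chrom)) {
      s <- seg[seg$chrom == chrom, , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
        stop("sample ", sample_id, ": overlapping segments on ", chrom)
    }
  }
  rownames(seg) <- NULL
  seg
}

#' @export
print.SegmentProfile <- function(x, ...) {
  cat("SegmentProfile", x$sample_id,
      if (!is.na(x$lesion)) paste0("(", x$lesion, ")") else "",
      "\n  segments:", nrow(x$segments),
      " purity:", x$purity, " ploidy:", x$ploidy, "\n")
  invisible(x)
}

#' Read a SEG-like segment table
#'
#' Expects a TSV with header \code{sample, chrom, start, end, major_cn,
#' minor_cn, cell_frac} and optional columns \code{lesion}, \code{purity},
#' \code{ploidy}. Rows failing the segment invariants raise an error naming
#' the offending row.
#'
#' @param path path to the TSV.
#' @return Named list of [segment_profile()] objects, one per sample.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("sample", "chrom", "start", "end", "major_cn", "minor_cn",
                "cell_frac")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("segment table missing column(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (sid in unique(tab$sample)) {
    rows <- tab[tab$sample == sid, , drop = FALSE]
    lesion <- if ("lesion" %in% names(rows)) rows$lesion[1L] else NA_character_
    purity <- if ("purity" %in% names(rows)) rows$purity[1L] else 1
    ploidy <- if ("ploidy" %in% names(rows)) rows$ploidy[1L] else 2
    out[[sid]] <- segment_profile(
      sample_id = as.character(sid),
      segments = rows[c("chrom", "start", "end", "major_cn", "minor_cn",
                        "cell_frac")],
      lesion = lesion, purity = purity, ploidy = ploidy)
  }
  out
}

#' Write segment profiles to a SEG-like TSV
#'
#' @param profiles list of \code{SegmentProfile} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "SegmentProfile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    s <- p$segments
    if (!nrow(s)) return(NULL)
    data.frame(sample = p$sample_id, lesion = p$lesion,
               purity = p$purity, ploidy = p$ploidy, s,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[c("sample", "lesion", "purity", "ploidy", "chrom", "start",
               "end", "major_cn", "minor_cn", "cell_frac")]
  tab$cell_frac <- fmt_num(tab$cell_frac)
  tab$purity <- fmt_num(tab$purity)
  tab$ploidy <- fmt_num(tab$ploidy)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed 6-significant-digit float format for byte-stable writers
fmt_num <- function(x) as.character(signif(as.numeric(x), 6))

#' Construct and validate a clone-tree document
#'
#' A rooted tree of clones with per-sample cancer cell fractions (CCFs) and
#' alteration assignments. The root is the normal clone and must have
#' exactly one child, the founder clone. Node CCFs are inclusive of
#' descendants, so a child's CCF may not exceed its parent's by more than a
#' small tolerance.
#'
#' @param patient_id patient identifier.
#' @param nodes data.frame with columns \code{id}, \code{parent} (\code{NA}
#'   for the root) and one \code{ccf_<sample>} column per sample label.
#' @param samples character vector of sample labels (default
#'   \code{c("primary", "relapse")}).
#' @param assignments named character vector mapping alteration ids to node
#'   ids (may be empty).
#' @return An object of class \code{TreeDocument}.
#' @export
tree_document <- function(patient_id, nodes, samples = LESIONS,
                          assignments = character()) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  ccf_cols <- paste0("ccf_", samples)
  missing <- setdiff(c("id", "parent", ccf_cols), names(nodes))
  if (length(missing))
    stop("tree nodes missing column(s): ", paste(missing, collapse = ", "))
  nodes <- nodes[c("id", "parent", ccf_cols)]
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  roots <- nodes$id[is.na(nodes$parent)]
  if (length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots))
  if (!all(stats::na.omit(nodes$parent) %in% nodes$id))
    stop("parent references unknown node")
  # cycle check by walking to the root from every node
  for (id in nodes$id) {
    seen <- character()
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle detected at node ", id)
      seen <- c(seen, cur)
      cur <- nodes$parent[match(cur, nodes$id)]
    }
  }
  if (sum(!is.na(nodes$parent) & nodes$parent == roots) != 1L)
    stop("root (normal clone) must have exactly one child, the founder")
  for (col in ccf_cols) {
    v <- as.numeric(nodes[[col]])
    if (anyNA(v) || any(v < 0 | v > 1))
      stop("CCFs in ", col, " must lie in [0, 1]")
    nodes[[col]] <- v
    pidx <- match(nodes$parent, nodes$id)
    has_parent <- !is.na(pidx)
    excess <- v[has_parent] - v[pidx[has_parent]]
    if (any(excess > CCF_MONOTONE_TOL))
      stop("child CCF exceeds parent CCF by more than ", CCF_MONOTONE_TOL,
           " in ", col)
  }
  if (length(assignments)) {
    assignments <- vapply(assignments, as.character, character(1L))
    if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
      stop("assignments must be named by alteration id")
    if (!all(assignments %in% nodes$id))
      stop("assignment references unknown node")
    assignments <- assignments[order(names(assignments))]
  }
  rownames(nodes) <- NULL
  structure(list(patient_id = patient_id, samples = samples, nodes = nodes,
                 assignments = assignments),
            class = "TreeDocument")
}

#' @export
print.TreeDocument <- function(x, ...) {
  cat("TreeDocument", x$patient_id, "-", nrow(x$nodes), "nodes,",
      length(x$assignments), "alterations, samples:",
      paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

tree_root <- function(tree) tree$nodes$id[is.na(tree$nodes$parent)]

tree_founder <- function(tree) {
  root <- tree_root(tree)
  tree$nodes$id[!is.na(tree$nodes$parent) & tree$nodes$parent == root]
}

tree_children <- function(tree, id)
  tree$nodes$id[!is.na(tree$nodes$parent) & tree$nodes$parent == id]

node_ccf <- function(tree, id, sample) {
  col <- paste0("ccf_", sample)
  if (!col %in% names(tree$nodes)) stop("unknown sample label: ", sample)
  tree$nodes[[col]][match(id, tree$nodes$id)]
}

#' Read / write clone-tree JSON
#'
#' The JSON schema is: \code{{"patient_id": str, "samples": [str...],
#' "nodes": [{"id": str, "parent": str|null, "ccf": {sample: num}}...],
#' "assignments": {alteration_id: node_id}}}. Floats are serialized with 6
#' significant digits; output is byte-stable.
#'
#' @param path file path.
#' @return [tree_document()] for \code{read_tree}; \code{path} invisibly for
#'   \code{write_tree}.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("patient_id", "samples", "nodes"))
    if (is.null(doc[[field]])) stop("tree JSON missing field: ", field)
  samples <- unlist(doc$samples)
  nodes <- do.call(rbind, lapply(doc$nodes, function(n) {
    row <- data.frame(id = as.character(n$id),
                      parent = if (is.null(n$parent)) NA_character_
                               else as.character(n$parent),
                      stringsAsFactors = FALSE)
    for (s in samples) {
      v <- n$ccf[[s]]
      row[[paste0("ccf_", s)]] <- if (is.null(v)) NA_real_ else as.numeric(v)
    }
    row
  }))
  assignments <- character()
  if (!is.null(doc$assignments) && length(doc$assignments)) {
    assignments <- vapply(doc$assignments, as.character, character(1L))
  }
  tree_document(doc$patient_id, nodes, samples, assignments)
}

#' @rdname read_tree
#' @param tree a \code{TreeDocument}.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "TreeDocument"))
  node_list <- lapply(seq_len(nrow(tree$nodes)), function(i) {
    r <- tree$nodes[i, ]
    ccf <- lapply(tree$samples,
                  function(s) signif(r[[paste0("ccf_", s)]], 6))
    names(ccf) <- tree$samples
    list(id = r$id,
         parent = if (is.na(r$parent)) NULL else r$parent,
         ccf = ccf)
  })
  doc <- list(patient_id = tree$patient_id,
              samples = as.list(tree$samples),
              nodes = node_list,
              assignments = if (length(tree$assignments))
                as.list(tree$assignments[order(names(tree$assignments))])
              else structure(list(), names = character()))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a MAF-lite mutation table
#'
#' Expects a TSV with columns \code{sample, lesion, gene, variant_class,
#' origin, ref, alt, five_prime, three_prime}. \code{variant_class} comes
#' from the closed vocabulary (missense, nonsense, frameshift, splice,
#' start_stop, silent, other); \code{origin} is germline or somatic.
#'
#' @param path path to the TSV.
#' @return data.frame of validated mutation records.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("mutation file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_mutations(tab)
}

validate_mutations <- function(tab) {
  required <- c("sample", "lesion", "gene", "variant_class", "origin",
                "ref", "alt", "five_prime", "three_prime")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("mutation table missing column(s): ", paste(missing, collapse = ", "))
  tab <- tab[required]
  bad_class <- !tab$variant_class %in% VARIANT_CLASSES
  if (any(bad_class))
    stop("unknown variant_class at row ", which(bad_class)[1L], ": ",
         tab$variant_class[which(bad_class)[1L]])
  bad_origin <- !tab$origin %in% c("germline", "somatic")
  if (any(bad_origin))
    stop("origin must be germline or somatic (row ",
         which(bad_origin)[1L], ")")
  bad_lesion <- !tab$lesion %in% LESIONS
  if (any(bad_lesion))
    stop("lesion must be primary or relapse (row ", which(bad_lesion)[1L], ")")
  rownames(tab) <- NULL
  tab
}

#' Write a mutation table
#' @param mutations data.frame as returned by [read_mutations()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference signature catalog
#'
#' TSV with a \code{context} column of the 96 trinucleotide context labels
#' (e.g. \code{A[C>T]G}) and one column per signature. Columns are
#' renormalized to sum to 1; a column whose sum deviates from 1 by more than
#' \code{tol} is rejected.
#'
#' @param path path to the TSV.
#' @param tol maximum allowed deviation of a column sum from 1.
#' @return numeric matrix, 96 contexts (rows, canonical order) x signatures.
#' @export
read_signature_catalog <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("signature catalog not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"context" %in% names(tab))
    stop("signature catalog needs a 'context' column")
  if (ncol(tab) < 2L) stop("signature catalog has no signature columns")
  labels <- context_labels()
  if (nrow(tab) != 96L)
    stop("signature catalog must have 96 context rows, found ", nrow(tab))
  if (!setequal(tab$context, labels))
    stop("signature catalog contexts do not match the canonical 96 labels")
  tab <- tab[match(labels, tab$context), , drop = FALSE]
  mat <- as.matrix(tab[, setdiff(names(tab), "context"), drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- labels
  if (any(mat < 0)) stop("signature catalog has negative entries")
  sums <- colSums(mat)
  off <- abs(sums - 1) > tol
  if (any(off))
    stop("signature column(s) not normalized to 1: ",
         paste(colnames(mat)[off], collapse = ", "))
  sweep(mat, 2L, sums, "/")
}

#' Write a signature catalog (or any context-by-signature matrix)
#' @param mat 96 x k numeric matrix with canonical context rownames.
#' @param path output path.
#' @param digits decimal digits to keep (10 keeps column sums within 1e-6).
#' @return \code{path}, invisibly.
#' @export
write_signature_catalog <- function(mat, path, digits = 10) {
  stopifnot(nrow(mat) == 96L)
  tab <- data.frame(context = rownames(mat),
                    round(mat, digits), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an actionability rule table
#'
#' TSV with columns \code{gene}, \code{alteration} (mutation or
#' amplification) and \code{level} (evidence level label). Stands in for a
#' versioned OncoKB-style knowledge base; no network access is ever made.
#'
#' @param path path to the TSV.
#' @return data.frame of rules.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "alteration", "level"), names(tab))
  if (length(missing))
    stop("rule table missing column(s): ", paste(missing, collapse = ", "))
  bad <- !tab$alteration %in% c("mutation", "amplification")
  if (any(bad))
    stop("rule alteration must be mutation or amplification (row ",
         which(bad)[1L], ")")
  tab
}

#' Read an HR-gene variant event table
#'
#' Long-format TSV with columns \code{sample, lesion, gene, event}, one row
#' per event, where \code{event} is one of germline_lof, germline_vus,
#' somatic_lof, somatic_vus, somatic_loh, deep_deletion.
#'
#' @param path path to the TSV.
#' @return data.frame of validated HR variant events.
#' @export
read_hr_variants <- function(path) {
  if (!file.exists(path)) stop("HR variant file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("sample", "lesion", "gene", "event"), names(tab))
  if (length(missing))
    stop("HR variant table missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- !tab$event %in% HR_EVENT_TYPES
  if (any(bad))
    stop("unknown HR event type at row ", which(bad)[1L], ": ",
         tab$event[which(bad)[1L]])
  bad_lesion <- !tab$lesion %in% LESIONS
  if (any(bad_lesion))
    stop("lesion must be primary or relapse (row ", which(bad_lesion)[1L], ")")
  tab
}

#' Read a clinical characteristics table
#'
#' TSV with columns \code{patient, age, grade, er, pr, her2, subtype,
#' relapse_months}; empty cells are missing data. Receptor statuses are
#' \code{+} or \code{-}.
#'
#' @param path path to the TSV.
#' @return data.frame of clinical records.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  required <- c("patient", "age", "grade", "er", "pr", "her2", "subtype",
                "relapse_months")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("er", "pr", "her2")) {
    ok <- is.na(tab[[col]]) | tab[[col]] %in% c("+", "-")
    if (!all(ok))
      stop(col, " status must be '+', '-' or missing (row ",
           which(!ok)[1L], ")")
  }
  tab
}
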