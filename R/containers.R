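#' Feature-by-sample log2 abundance table
#'
#' The basic quantitative container used throughout the pipeline: a numeric
#' matrix of log2 abundances (features in rows, samples in columns) together
#' with a per-sample phenotype group factor and an omics tag.
#'
#' @param values Numeric matrix, features x samples, with row and column
#'   names.  Values are log2 abundances (log2 copy numbers for miRNAs, log2
#'   intensities for proteins).
#' @param groups Factor (or coercible) of length `ncol(values)` giving the
#'   phenotype group of each sample.
#' @param omics One of `"mirna"` or `"protein"`.
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values`, `groups` and `omics`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' a <- abundance_matrix(x, rep(c("A", "B"), each = 2), "protein")
#' @export
abundance_matrix <- function(values, groups, omics = c("mirna", "protein")) {
  omics <- match.arg(omics)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("sample IDs must be unique")
  if (anyDuplicated(rownames(values)))
    stop("feature IDs must be unique")
  groups <- as.factor(groups)
  if (length(groups) != ncol(values))
    stop("`groups` must have one entry per sample")
  if (any(is.na(groups)) || any(!nzchar(as.character(groups))))
    stop("group labels must be non-empty")
  structure(list(values = values, groups = groups, omics = omics),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %s: %d features x %d samples (%s)\n",
              x$omics, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Peptide-by-sample intensity table with peptide-to-protein map
#'
#' Linear-scale peptide intensities as delivered by an LC-MS pipeline after
#' identification and alignment; missing values are allowed (NA).  Each
#' peptide maps to exactly one protein.
#'
#' @param intensities Numeric matrix, peptides x samples, linear scale,
#'   `NA` for missing cells.
#' @param map Data frame with columns `peptide` and `protein`; every row of
#'   `intensities` must appear exactly once in `map$peptide`.
#' @param groups Factor of per-sample group labels.
#' @return Object of class `peptide_matrix`.
#' @export
peptide_matrix <- function(intensities, map, groups) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix")
  if (nrow(intensities) > 0 &&
      (is.null(rownames(intensities)) || is.null(colnames(intensities))))
    stop("`intensities` must have peptide rownames and sample colnames")
  if (!is.data.frame(map) || !all(c("peptide", "protein") %in% names(map)))
    stop("`map` must be a data.frame with columns peptide, protein")
  if (anyDuplicated(map$peptide))
    stop("every peptide must map to exactly one protein")
  if (!setequal(rownames(intensities), map$peptide))
    stop("peptide map must cover exactly the rows of the intensity matrix")
  groups <- as.factor(groups)
  if (length(groups) != ncol(intensities))
    stop("`groups` must have one entry per sample")
  map <- map[match(rownames(intensities), map$peptide), , drop = FALSE]
  rownames(map) <- NULL
  structure(list(intensities = intensities, map = map, groups = groups),
            class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf(
    "<peptide_matrix> %d peptides / %d proteins x %d samples (%.1f%% missing)\n",
    nrow(x$intensities), length(unique(x$map$protein)), ncol(x$intensities),
    100 * mean(is.na(x$intensities))))
  invisible(x)
}

# canonical edge identifier; protein-protein endpoints sorted so positive
# edges are order-invariant
edge_id <- function(node1, node2, sign) {
  swap <- sign > 0 & node2 < node1
  tmp <- node1[swap]
  node1[swap] <- node2[swap]
  node2[swap] <- tmp
  sprintf("%s|%s|%+d", node1, node2, as.integer(sign))
}

#' Signed molecular interaction network
#'
#' Edge list over miRNA and protein nodes.  Negative edges (sign -1) are
#' repressive miRNA-to-target relations (the miRNA endpoint is stored as
#' `node1`); positive edges (sign +1) join two proteins (endpoints stored in
#' lexicographic order so the edge is orientation-free).
#'
#' @param edges Data frame with columns `node1`, `node2`, `sign`
#'   (values +1 or -1).  Extra columns are preserved.
#' @param node_type Named character vector mapping every node identifier to
#'   `"mirna"` or `"protein"`.
#' @return Object of class `signed_network` with elements `edges` (including
#'   a canonical `edge_id` column) and `node_type`.
#' @export
signed_network <- function(edges, node_type) {
  if (!is.data.frame(edges) ||
      !all(c("node1", "node2", "sign") %in% names(edges)))
    stop("`edges` must have columns node1, node2, sign")
  edges$node1 <- as.character(edges$node1)
  edges$node2 <- as.character(edges$node2)
  edges$sign <- as.integer(edges$sign)
  if (!all(edges$sign %in% c(-1L, 1L)))
    stop("edge sign must be +1 or -1")
  if (any(edges$node1 == edges$node2))
    stop("self-loops are not allowed")
  nodes <- unique(c(edges$node1, edges$node2))
  if (!all(nodes %in% names(node_type)))
    stop("`node_type` must cover every node in the edge list")
  node_type <- node_type[nodes]
  if (!all(node_type %in% c("mirna", "protein")))
    stop("node types must be 'mirna' or 'protein'")

  t1 <- unname(node_type[edges$node1])
  t2 <- unname(node_type[edges$node2])
  neg <- edges$sign == -1L
  # orient negative edges miRNA -> protein
  flip <- neg & t1 == "protein" & t2 == "mirna"
  tmp <- edges$node1[flip]
  edges$node1[flip] <- edges$node2[flip]
  edges$node2[flip] <- tmp
  t1 <- unname(node_type[edges$node1])
  t2 <- unname(node_type[edges$node2])
  bad_neg <- neg & !(t1 == "mirna" & t2 == "protein")
  bad_pos <- !neg & !(t1 == "protein" & t2 == "protein")
  if (any(bad_neg))
    stop(sprintf("negative edges must join one miRNA and one protein (%d bad)",
                 sum(bad_neg)))
  if (any(bad_pos))
    stop(sprintf("positive edges must join two proteins (%d bad)",
                 sum(bad_pos)))
  edges$edge_id <- edge_id(edges$node1, edges$node2, edges$sign)
  # re-read endpoints from the canonical id so sorted PPI order is stored
  canon <- do.call(rbind, strsplit(edges$edge_id, "|", fixed = TRUE))
  edges$node1 <- canon[, 1]
  edges$node2 <- canon[, 2]
  if (anyDuplicated(edges$edge_id)) {
    dup <- unique(edges$edge_id[duplicated(edges$edge_id)])
    stop(sprintf("duplicate edges: %s",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, node_type = node_type),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf(
    "<signed_network> %d edges (%d miRNA->protein, %d PPI) over %d miRNAs, %d proteins\n",
    nrow(x$edges), sum(x$edges$sign == -1L), sum(x$edges$sign == 1L),
    sum(x$node_type == "mirna"), sum(x$node_type == "protein")))
  invisible(x)
}
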