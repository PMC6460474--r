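#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, "", 1))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Description field (2nd GMT column); recycled.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per gene set: with a universe of `N`
#' genes, `K` of which belong to the set, and a selection of `n` genes
#' containing `k` set members, `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.  Gene sets are intersected with the
#' universe first; results are sorted by p with a nominal significance
#' column at `p < 0.05`.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector: all quantified genes.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param alpha Nominal significance level; default 0.05.
#' @param adjust Apply Benjamini-Hochberg to the p-values (extra `p_adj`
#'   column)?  Default `FALSE` (nominal p, as is conventional for
#'   exploratory enrichment figures).
#' @return Data frame: `set`, `N`, `K`, `n`, `k`, `p`, `significant`,
#'   `overlap` (comma-joined gene IDs), sorted by `p`.
#' @export
hypergeometric_enrichment <- function(selected, universe, sets,
                                      alpha = 0.05, adjust = FALSE) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (!length(universe)) stop("empty universe")
  if (!length(selected)) stop("empty selection")
  if (!all(selected %in% universe))
    stop("`selected` must be a subset of `universe`")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    K <- length(set)
    hit <- intersect(selected, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, N = N, K = K, n = n, k = k, p = p,
               overlap = paste(sort(hit), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$set), , drop = FALSE]
  out$significant <- out$p < alpha
  if (adjust) out$p_adj <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Tissue-of-origin calls for genes
#'
#' A gene is considered to originate from a tissue if that tissue has
#' evidence of **both** mRNA and protein expression.  Genes whose origin
#' set contains an adipose-type tissue are flagged adipose-dependent
#' (obesity-dependent) candidates; genes with a non-empty, non-adipose,
#' non-ubiquitous origin set are adipose-independent; empty or
#' vocabulary-wide origin sets are ubiquitous/unresolved.
#'
#' @param genes Character vector of gene IDs to call.
#' @param annot Data frame with columns `gene`, `tissue`, `rna_evidence`,
#'   `protein_evidence` (see [generate_annotations()]).
#' @param adipose_tissues Tissue names counted as adipose; default
#'   `"adipose"`.
#' @return Data frame: `gene`, `origin` (comma-joined tissues),
#'   `n_origin`, `exclusive` (exactly one origin tissue),
#'   `obesity_dependence` in
#'   \{`adipose-dependent`, `adipose-independent`, `ubiquitous/unresolved`\}.
#' @export
call_origin <- function(genes, annot, adipose_tissues = "adipose") {
  stopifnot(all(c("gene", "tissue", "rna_evidence", "protein_evidence")
                %in% names(annot)))
  vocab <- unique(annot$tissue)
  missing <- setdiff(genes, annot$gene)
  if (length(missing))
    warning(sprintf("%d gene(s) absent from the annotation; returned unresolved",
                    length(missing)))
  both <- annot[annot$rna_evidence & annot$protein_evidence, c("gene", "tissue")]
  origins <- split(both$tissue, factor(both$gene, levels = unique(genes)))
  rows <- lapply(genes, function(g) {
    tis <- sort(unique(origins[[g]]))
    n_or <- length(tis)
    label <- if (g %in% missing || n_or == 0 || n_or == length(vocab))
      "ubiquitous/unresolved"
    else if (any(tis %in% adipose_tissues)) "adipose-dependent"
    else "adipose-independent"
    data.frame(gene = g, origin = paste(tis, collapse = ","),
               n_origin = n_or, exclusive = n_or == 1,
               obesity_dependence = label)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label subnetwork edges with tissue-of-origin information
#'
#' Each repressive (miRNA->protein) edge is labeled with its target
#' protein's origin call — the candidate site of the miRNA's regulatory
#' action; each PPI edge with the intersection of its two proteins' origin
#' sets.  Edges whose proteins have no resolved origin are labeled
#' `unresolved`.
#'
#' @param sub A [extract_subnetwork()] result.
#' @param origins A [call_origin()] result covering the subnetwork's
#'   proteins.
#' @param adipose_tissues Tissue names counted as adipose; default
#'   `"adipose"`.
#' @return The subnetwork edge table with `origin` and
#'   `obesity_dependence` columns.
#' @export
annotate_subnetwork <- function(sub, origins, adipose_tissues = "adipose") {
  stopifnot(inherits(sub, "predictive_subnetwork"),
            all(c("gene", "origin", "obesity_dependence") %in% names(origins)))
  e <- sub$edges
  if (!nrow(e)) return(cbind(e, origin = character(0),
                             obesity_dependence = character(0)))
  olist <- stats::setNames(strsplit(origins$origin, ",", fixed = TRUE),
                           origins$gene)
  odep <- stats::setNames(origins$obesity_dependence, origins$gene)
  lab <- character(nrow(e))
  dep <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    if (e$sign[i] == -1L) {
      tis <- olist[[e$node2[i]]]
      dep[i] <- if (!is.null(odep[e$node2[i]]) && !is.na(odep[e$node2[i]]))
        odep[[e$node2[i]]] else "ubiquitous/unresolved"
    } else {
      tis <- intersect(olist[[e$node1[i]]], olist[[e$node2[i]]])
      dep[i] <- if (length(tis) == 0) "ubiquitous/unresolved"
        else if (any(tis %in% adipose_tissues)) "adipose-dependent"
        else "adipose-independent"
    }
    tis <- tis[nzchar(tis)]
    lab[i] <- if (length(tis)) paste(sort(tis), collapse = ",") else "unresolved"
  }
  e$origin <- lab
  e$obesity_dependence <- dep
  e
}
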