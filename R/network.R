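#' Read a signed edge list from a tab-delimited file
#'
#' Expects three tab-separated columns (`node1`, `node2`, `sign` with sign
#' in \{+1, -1\}); a header row and `#`-prefixed comment lines are
#' tolerated.  Node types are taken from `node_types` when given, otherwise
#' inferred from the identifier (`mirna_pattern`).  All violations —
#' malformed sign, type-inconsistent edges, duplicates — are collected into
#' a validation report naming the offending lines, and any violation is
#' fatal.
#'
#' @param path Path to the edge-list file.
#' @param node_types Optional named vector mapping node IDs to
#'   `"mirna"`/`"protein"`.
#' @param mirna_pattern Regex used to recognize miRNA identifiers when
#'   `node_types` is absent; default matches `miR-`/`let-`-style names.
#' @return A [signed_network()].
#' @export
load_network <- function(path, node_types = NULL,
                         mirna_pattern = "^(hsa-)?(miR|mir|let)\\b|^(hsa-)?(miR|mir|let)-") {
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("edge list must have 3 tab-delimited columns")
  raw <- raw[, 1:3]
  names(raw) <- c("node1", "node2", "sign")
  if (identical(tolower(as.character(raw[1, ])),
                c("node1", "node2", "sign")))
    raw <- raw[-1, , drop = FALSE]
  raw$line <- seq_len(nrow(raw))
  raw$sign_num <- suppressWarnings(as.integer(raw$sign))

  problems <- character(0)
  bad_sign <- is.na(raw$sign_num) | !(raw$sign_num %in% c(-1L, 1L))
  if (any(bad_sign))
    problems <- c(problems,
                  sprintf("line %d: sign '%s' not in {+1,-1}",
                          raw$line[bad_sign], raw$sign[bad_sign]))

  nodes <- unique(c(raw$node1, raw$node2))
  if (is.null(node_types)) {
    node_types <- stats::setNames(
      ifelse(grepl(mirna_pattern, nodes), "mirna", "protein"), nodes)
  } else if (!all(nodes %in% names(node_types))) {
    stop("`node_types` must cover every node in the file")
  }
  t1 <- unname(node_types[raw$node1])
  t2 <- unname(node_types[raw$node2])
  neg <- !is.na(raw$sign_num) & raw$sign_num == -1L
  pos <- !is.na(raw$sign_num) & raw$sign_num == 1L
  bad_neg <- neg & !((t1 == "mirna" & t2 == "protein") |
                     (t1 == "protein" & t2 == "mirna"))
  bad_pos <- pos & !(t1 == "protein" & t2 == "protein")
  if (any(bad_neg))
    problems <- c(problems,
                  sprintf("line %d: negative edge %s--%s does not join a miRNA and a protein",
                          raw$line[bad_neg], raw$node1[bad_neg], raw$node2[bad_neg]))
  if (any(bad_pos))
    problems <- c(problems,
                  sprintf("line %d: positive edge %s--%s does not join two proteins",
                          raw$line[bad_pos], raw$node1[bad_pos], raw$node2[bad_pos]))
  loops <- raw$node1 == raw$node2
  if (any(loops))
    problems <- c(problems, sprintf("line %d: self-loop %s",
                                    raw$line[loops], raw$node1[loops]))

  ok <- !bad_sign & !bad_neg & !bad_pos & !loops
  ids <- rep(NA_character_, nrow(raw))
  ids[ok] <- edge_id(raw$node1[ok], raw$node2[ok], raw$sign_num[ok])
  dup <- ok & duplicated(ids) & !is.na(ids)
  if (any(dup))
    problems <- c(problems,
                  sprintf("line %d: duplicate edge %s", raw$line[dup], ids[dup]))
  if (length(problems))
    stop(paste(c("invalid network file:", problems), collapse = "\n  "))

  signed_network(data.frame(node1 = raw$node1, node2 = raw$node2,
                            sign = raw$sign_num),
                 node_types)
}

#' Write a signed network as a 3-column tab-delimited edge list
#'
#' @param net A [signed_network()].
#' @param path Output path.
#' @param provenance Optional character vector of `#`-prefixed header lines.
#' @export
write_network <- function(net, path, provenance = NULL) {
  stopifnot(inherits(net, "signed_network"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines("node1\tnode2\tsign", con)
  writeLines(sprintf("%s\t%s\t%+d", net$edges$node1, net$edges$node2,
                     net$edges$sign), con)
  invisible(path)
}

#' Restrict a network to measured features
#'
#' Drops every edge with an endpoint absent from the corresponding Z-score
#' matrix and reports the dropped counts by reason via `message()`.
#'
#' @param net A [signed_network()].
#' @param z_m miRNA `zscore_matrix`.
#' @param z_p Protein `zscore_matrix`.
#' @return The restricted [signed_network()] (planted flags preserved).
#' @export
restrict_to_measured <- function(net, z_m, z_p) {
  stopifnot(inherits(net, "signed_network"),
            inherits(z_m, "zscore_matrix"), inherits(z_p, "zscore_matrix"))
  if (!identical(colnames(z_m$values), colnames(z_p$values)))
    stop("sample IDs of the two Z-score matrices must match in order")
  mir_meas <- rownames(z_m$values)
  prot_meas <- rownames(z_p$values)
  e <- net$edges
  neg <- e$sign == -1L
  keep <- ifelse(neg,
                 e$node1 %in% mir_meas & e$node2 %in% prot_meas,
                 e$node1 %in% prot_meas & e$node2 %in% prot_meas)
  n_drop_neg <- sum(!keep & neg)
  n_drop_pos <- sum(!keep & !neg)
  if (n_drop_neg + n_drop_pos > 0)
    message(sprintf(
      "restrict_to_measured: dropped %d miRNA->protein and %d PPI edge(s) with unmeasured endpoints",
      n_drop_neg, n_drop_pos))
  if (!any(keep)) stop("no edges remain after restriction to measured features")
  out <- net
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  nodes <- unique(c(out$edges$node1, out$edges$node2))
  out$node_type <- net$node_type[nodes]
  out
}

#' Per-sample edge co-expression scores
#'
#' For sample `j`, a repressive edge (miRNA `m`, protein `p`) scores
#' `e = z_pj - z_mj` (high when the protein is above and the miRNA below
#' their means), and a cooperative protein-protein edge scores
#' `e = z_p1j + z_p2j`.  With `scale = TRUE` scores are divided by
#' `sqrt(2)` so that independent unit-variance endpoints give unit-variance
#' edges; the default follows the plain difference/sum formulas.
#'
#' @param net A [signed_network()] restricted to measured nodes.
#' @param z_m miRNA `zscore_matrix`.
#' @param z_p Protein `zscore_matrix` (same samples, same order).
#' @param scale Divide scores by `sqrt(2)`?  Default `FALSE`.
#' @return Object of class `edge_score_matrix`: list with `scores`
#'   (edges x samples, rownames = canonical edge IDs), `edges` (the edge
#'   table), `groups`, `scaled`.
#' @export
edge_scores <- function(net, z_m, z_p, scale = FALSE) {
  stopifnot(inherits(net, "signed_network"),
            inherits(z_m, "zscore_matrix"), inherits(z_p, "zscore_matrix"))
  if (!identical(colnames(z_m$values), colnames(z_p$values)))
    stop("sample IDs of the two Z-score matrices must match in order")
  if (!identical(as.character(z_m$groups), as.character(z_p$groups)))
    stop("group labels of the two Z-score matrices must match")
  e <- net$edges
  miss_m <- e$sign == -1L & !(e$node1 %in% rownames(z_m$values))
  miss_p <- (e$sign == -1L & !(e$node2 %in% rownames(z_p$values))) |
    (e$sign == 1L & !(e$node1 %in% rownames(z_p$values) &
                      e$node2 %in% rownames(z_p$values)))
  if (any(miss_m | miss_p))
    stop("network has unmeasured endpoints; run restrict_to_measured() first")
  neg <- e$sign == -1L
  sc <- matrix(NA_real_, nrow(e), ncol(z_p$values),
               dimnames = list(e$edge_id, colnames(z_p$values)))
  if (any(neg))
    sc[neg, ] <- z_p$values[e$node2[neg], , drop = FALSE] -
      z_m$values[e$node1[neg], , drop = FALSE]
  if (any(!neg))
    sc[!neg, ] <- z_p$values[e$node1[!neg], , drop = FALSE] +
      z_p$values[e$node2[!neg], , drop = FALSE]
  if (scale) sc <- sc / sqrt(2)
  structure(list(scores = sc, edges = e, groups = z_p$groups,
                 scaled = scale),
            class = "edge_score_matrix")
}

#' @export
print.edge_score_matrix <- function(x, ...) {
  cat(sprintf("<edge_score_matrix> %d edges x %d samples%s\n",
              nrow(x$scores), ncol(x$scores),
              if (x$scaled) " (1/sqrt(2)-scaled)" else ""))
  invisible(x)
}
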