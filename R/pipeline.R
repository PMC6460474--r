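# ---- provenance-aware TSV I/O -----------------------------------------------

config_md5 <- function(config) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

provenance_lines <- function(config, stage) {
  c(sprintf("omicsPAM %s", as.character(utils::packageVersion("omicsPAM"))),
    sprintf("stage=%s", stage),
    sprintf("seed=%d", config$seed),
    sprintf("config_md5=%s", config_md5(config)))
}

write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(mat, path, provenance = NULL,
                             id_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path, provenance)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# ---- run configuration ------------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run with the study defaults:
#' nominal miRNA p < 0.01, protein q < 0.05, 10 sets of fivefold
#' cross-validation over a 30-point shrinkage grid, Welch tests, unscaled
#' edge scores, and KNN imputation with k = 6.
#'
#' @param synthetic A [synthetic_config()] describing the cohort.
#' @param seed Master seed; defaults to `synthetic$seed`.
#' @param mirna_p Nominal p threshold for miRNA candidates (0, 1).
#' @param protein_q q threshold for protein candidates (0, 1).
#' @param n_repeats,n_folds Cross-validation design; defaults 10 x 5.
#' @param scale_edges Divide edge scores by sqrt(2)?  Default `FALSE`.
#' @param test_variant `"welch"` or `"pooled"` t-test.
#' @param mk_variant `"exact"` or `"plus"` class-size factor (see
#'   [nsc_fit()]).
#' @param prior `"empirical"` or `"uniform"` class priors.
#' @param knn_k Neighbour count for peptide imputation.
#' @param prefilter Restrict edge integration to differential candidates?
#'   Default `FALSE` (full matrices enter the integration).
#' @param adipose_tissues Tissue names counted as adipose in origin triage.
#' @param make_plot Write the CV error-curve PDF?  Default `TRUE`.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(), seed = NULL,
                       mirna_p = 0.01, protein_q = 0.05,
                       n_repeats = 10, n_folds = 5,
                       scale_edges = FALSE,
                       test_variant = c("welch", "pooled"),
                       mk_variant = c("exact", "plus"),
                       prior = c("empirical", "uniform"),
                       knn_k = 6, prefilter = FALSE,
                       adipose_tissues = "adipose",
                       make_plot = TRUE) {
  if (!inherits(synthetic, "synthetic_config"))
    synthetic <- do.call(synthetic_config, as.list(synthetic))
  cfg <- list(synthetic = synthetic,
              seed = as.integer(if (is.null(seed)) synthetic$seed else seed),
              mirna_p = mirna_p, protein_q = protein_q,
              n_repeats = as.integer(n_repeats),
              n_folds = as.integer(n_folds),
              scale_edges = isTRUE(scale_edges),
              test_variant = match.arg(test_variant),
              mk_variant = match.arg(mk_variant),
              prior = match.arg(prior),
              knn_k = as.integer(knn_k),
              prefilter = isTRUE(prefilter),
              adipose_tissues = adipose_tissues,
              make_plot = isTRUE(make_plot))
  if (cfg$mirna_p <= 0 || cfg$mirna_p >= 1)
    stop("`mirna_p` must be in (0, 1)")
  if (cfg$protein_q <= 0 || cfg$protein_q >= 1)
    stop("`protein_q` must be in (0, 1)")
  if (cfg$n_repeats < 1) stop("`n_repeats` must be >= 1")
  if (cfg$n_folds < 2) stop("`n_folds` must be >= 2")
  if (cfg$knn_k < 1) stop("`knn_k` must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Top-level keys are [run_config()] arguments; the `synthetic` key holds
#' [synthetic_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic))
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  do.call(run_config, y)
}

# ---- simulate stage ---------------------------------------------------------

#' Generate and write the full synthetic fixture bundle
#'
#' Runs every generator of the synthetic-data module and writes the bundle
#' to disk: the signed network (3-column edge list), true log2 abundance
#' matrices, raw qPCR plate tables, raw peptide table with map, tissue
#' annotations, gene sets (GMT), clinical records, sample sheet, and the
#' ground-truth record (JSON).  Idempotent for a fixed config.
#'
#' @param config A [run_config()] (or [synthetic_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and `files`.
#' @export
run_simulate <- function(config, out_dir) {
  if (inherits(config, "synthetic_config")) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$synthetic
  prov <- provenance_lines(config, "simulate")

  net <- generate_networks(sc)
  cohort <- generate_cohort(sc, net)
  plate <- generate_qpcr_plate(cohort$mirna, sc)
  peptides <- generate_peptide_table(cohort$protein, sc)
  annots <- generate_annotations(net, sc)
  clinical <- generate_clinical(sc)

  p <- function(f) file.path(out_dir, f)
  write_network(net, p("network.tsv"), provenance = prov)
  write_tsv(data.frame(sample = colnames(cohort$mirna$values),
                       group = as.character(cohort$mirna$groups)),
            p("samples.tsv"), prov)
  write_matrix_tsv(cohort$mirna$values, p("mirna_true_log2.tsv"), prov)
  write_matrix_tsv(cohort$protein$values, p("protein_true_log2.tsv"), prov)
  write_tsv(plate$samples, p("qpcr_samples.tsv"), prov)
  write_tsv(plate$standards, p("qpcr_standards.tsv"), prov)
  write_tsv(plate$ntc, p("qpcr_ntc.tsv"), prov)
  write_matrix_tsv(peptides$intensities, p("peptides.tsv"), prov,
                   id_col = "peptide")
  write_tsv(peptides$map, p("peptide_map.tsv"), prov)
  write_tsv(annots$tissue, p("tissue_annotations.tsv"), prov)
  write_gmt(annots$gene_sets, p("gene_sets.gmt"))
  write_tsv(clinical, p("clinical.tsv"), prov)
  jsonlite::write_json(
    list(signal_edges = cohort$truth$signal_edges,
         signal_features = cohort$truth$signal_features,
         config_seed = sc$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- c("network.tsv", "samples.tsv", "mirna_true_log2.tsv",
             "protein_true_log2.tsv", "qpcr_samples.tsv",
             "qpcr_standards.tsv", "qpcr_ntc.tsv", "peptides.tsv",
             "peptide_map.tsv", "tissue_annotations.tsv", "gene_sets.gmt",
             "clinical.tsv", "truth.json")
  invisible(list(network = net, cohort = cohort, plate = plate,
                 peptides = peptides, annotations = annots,
                 clinical = clinical,
                 files = file.path(out_dir, files)))
}

# reconstruct the in-memory bundle from a run_simulate() directory
read_bundle <- function(in_dir) {
  p <- function(f) file.path(in_dir, f)
  for (f in c("network.tsv", "samples.tsv", "qpcr_samples.tsv",
              "qpcr_standards.tsv", "qpcr_ntc.tsv", "peptides.tsv",
              "peptide_map.tsv", "tissue_annotations.tsv", "gene_sets.gmt"))
    if (!file.exists(p(f))) stop(sprintf("missing input file: %s", f))
  samples <- utils::read.delim(p("samples.tsv"), comment.char = "#")
  groups <- factor(samples$group)
  net <- load_network(p("network.tsv"))
  plate <- structure(
    list(samples = utils::read.delim(p("qpcr_samples.tsv"), comment.char = "#"),
         standards = utils::read.delim(p("qpcr_standards.tsv"), comment.char = "#"),
         ntc = utils::read.delim(p("qpcr_ntc.tsv"), comment.char = "#"),
         groups = groups, sample_ids = samples$sample,
         params = list()),
    class = "qpcr_plate")
  pep <- peptide_matrix(read_matrix_tsv(p("peptides.tsv")),
                        utils::read.delim(p("peptide_map.tsv"),
                                          comment.char = "#"),
                        groups)
  annots <- list(tissue = utils::read.delim(p("tissue_annotations.tsv"),
                                            comment.char = "#"),
                 gene_sets = read_gmt(p("gene_sets.gmt")))
  truth <- if (file.exists(p("truth.json")))
    jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  list(network = net, plate = plate, peptides = pep,
       annotations = annots, truth = truth, groups = groups)
}

# ---- full pipeline ----------------------------------------------------------

#' Run the full integrative analysis end to end
#'
#' Executes preprocess (qPCR quantification + normalization; peptide
#' filter, KNN imputation, median normalization, protein roll-up),
#' per-feature differential testing with q-values, Z-scoring, signed-edge
#' co-expression scoring, repeated cross-validated shrunken-centroid
#' threshold selection, predictive-subnetwork extraction, hypergeometric
#' enrichment, and tissue-of-origin triage; writes all report files plus a
#' machine-readable run summary.
#'
#' @param config A [run_config()].
#' @param out_dir Report directory (created if needed).
#' @param in_dir Optional directory holding a [run_simulate()] bundle; when
#'   `NULL` (default) the synthetic bundle is generated in memory from
#'   `config$synthetic`.
#' @return Invisibly, a list with all intermediate objects and the
#'   `summary` list.
#' @export
run_full <- function(config, out_dir, in_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance_lines(config, "run_full")
  p <- function(f) file.path(out_dir, f)

  bundle <- if (is.null(in_dir)) {
    sc <- config$synthetic
    net <- generate_networks(sc)
    cohort <- generate_cohort(sc, net)
    list(network = net,
         plate = generate_qpcr_plate(cohort$mirna, sc),
         peptides = generate_peptide_table(cohort$protein, sc),
         annotations = generate_annotations(net, sc),
         truth = cohort$truth)
  } else read_bundle(in_dir)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # -- preprocess
  mirna <- stage("preprocess/mirna", {
    q <- quantify_qpcr(bundle$plate)
    normalize_mirna(impute_undetected(q))
  })
  protein <- stage("preprocess/protein", {
    pep <- filter_peptides(bundle$peptides)
    pep <- impute_knn(pep, k = config$knn_k)
    pep <- normalize_median(pep)
    rollup_protein(pep)
  })

  # -- differential abundance + PCA
  dd <- stage("diffexp", {
    mt <- suppressWarnings(diff_test(mirna, config$test_variant))
    pt <- diff_test(protein, config$test_variant)
    sel <- select_candidates(mt, pt, config$mirna_p, config$protein_q)
    list(sel = sel,
         pca_mirna = pca_variance(mirna),
         pca_protein = pca_variance(protein))
  })

  # -- network integration
  integ <- stage("network_scores", {
    z_m <- zscore(mirna)
    z_p <- zscore(protein)
    if (config$prefilter) {
      keep_m <- dd$sel$mirna$feature[dd$sel$mirna$selected]
      keep_p <- dd$sel$protein$feature[dd$sel$protein$selected]
      z_m$values <- z_m$values[rownames(z_m$values) %in% keep_m, , drop = FALSE]
      z_p$values <- z_p$values[rownames(z_p$values) %in% keep_p, , drop = FALSE]
    }
    net_r <- suppressMessages(restrict_to_measured(bundle$network, z_m, z_p))
    list(net = net_r, scores = edge_scores(net_r, z_m, z_p,
                                           scale = config$scale_edges))
  })

  # -- classifier
  cv <- stage("edge_classifier", {
    nsc_cv(integ$scores, n_repeats = config$n_repeats,
           n_folds = config$n_folds, seed = config$seed,
           prior = config$prior, mk_variant = config$mk_variant)
  })
  sub <- stage("edge_classifier", {
    suppressWarnings(extract_subnetwork(cv$model, integ$net))
  })

  # -- annotation
  ann <- stage("annotation", {
    sub_prot <- unique(sub$nodes$node[sub$nodes$type == "protein"])
    enr <- if (length(sub_prot))
      hypergeometric_enrichment(sub_prot, rownames(protein$values),
                                bundle$annotations$gene_sets)
    origins <- if (length(sub_prot))
      call_origin(sub_prot, bundle$annotations$tissue,
                  config$adipose_tissues)
    report <- if (length(sub_prot))
      annotate_subnetwork(sub, origins, config$adipose_tissues)
    list(enrichment = enr, origins = origins, report = report)
  })

  # -- recovery metrics against planted truth, when available
  recovery <- NULL
  if (!is.null(bundle$truth)) {
    planted <- bundle$truth$signal_edges
    selected <- sub$edges$edge_id
    recovery <- list(
      n_planted = length(planted),
      n_selected = length(selected),
      recall = if (length(planted))
        length(intersect(selected, planted)) / length(planted) else NA,
      fdp = if (length(selected))
        length(setdiff(selected, planted)) / length(selected) else 0)
  }

  # -- outputs
  write_tsv(dd$sel$mirna, p("mirna_candidates.tsv"), prov)
  write_tsv(dd$sel$protein, p("protein_candidates.tsv"), prov)
  write_tsv(data.frame(delta = cv$grid, mean_error = cv$mean_error),
            p("cv_error_curve.tsv"), prov)
  write_tsv(data.frame(sample = rownames(cv$cv_posterior),
                       group = as.character(integ$scores$groups),
                       cv$cv_posterior,
                       cv_class = as.character(cv$cv_class),
                       check.names = FALSE),
            p("cv_posteriors.tsv"), prov)
  if (config$make_plot) {
    grDevices::pdf(p("cv_error_curve.pdf"), width = 6, height = 4)
    graphics::plot(cv$grid, cv$mean_error, type = "b", pch = 16,
                   xlab = expression(Delta),
                   ylab = "mean CV misclassification error",
                   main = sprintf("%d x %d-fold CV", cv$n_repeats, cv$n_folds))
    graphics::abline(v = cv$best_delta, lty = 2)
    grDevices::dev.off()
  }
  write_tsv(if (is.null(ann$report)) sub$edges else ann$report,
            p("subnetwork_edges.tsv"), prov)
  if (!sub$empty)
    export_cytoscape(sub, out_dir, origins = ann$origins)
  if (!is.null(ann$enrichment))
    write_tsv(ann$enrichment, p("enrichment.tsv"), prov)
  if (!is.null(ann$origins))
    write_tsv(ann$origins, p("origin_calls.tsv"), prov)

  summary <- list(
    provenance = list(package = "omicsPAM",
                      version = as.character(utils::packageVersion("omicsPAM")),
                      seed = config$seed,
                      config_md5 = config_md5(config)),
    candidates = list(
      n_mirna = sum(dd$sel$mirna$selected),
      n_mirna_up = sum(dd$sel$mirna$selected & dd$sel$mirna$direction == "up"),
      n_mirna_down = sum(dd$sel$mirna$selected & dd$sel$mirna$direction == "down"),
      n_protein = sum(dd$sel$protein$selected),
      n_protein_up = sum(dd$sel$protein$selected & dd$sel$protein$direction == "up"),
      n_protein_down = sum(dd$sel$protein$selected & dd$sel$protein$direction == "down")),
    pca = list(
      mirna_pc1_frac = unname(dd$pca_mirna$var_frac[1]),
      protein_pc1_frac = unname(dd$pca_protein$var_frac[1])),
    network = list(total_edges = nrow(integ$net$edges)),
    classifier = list(
      chosen_threshold = cv$best_delta,
      min_mean_cv_error = cv$best_error,
      selected = list(total = sub$counts$total,
                      mirna_protein = sub$counts$mirna_protein,
                      ppi = sub$counts$ppi)),
    recovery = recovery)
  jsonlite::write_json(summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = config, bundle = bundle, mirna = mirna,
                 protein = protein, diffexp = dd, integration = integ,
                 cv = cv, subnetwork = sub, annotation = ann,
                 recovery = recovery, summary = summary,
                 out_dir = out_dir))
}

# ---- network-viewer export --------------------------------------------------

#' Export a predictive subnetwork for network viewers
#'
#' Writes a SIF file (interaction types `represses` for miRNA->protein
#' edges and `binds` for PPIs, protein pairs in canonical sorted order)
#' plus node- and edge-attribute TSVs.
#'
#' @param sub A [extract_subnetwork()] result.
#' @param dir Output directory.
#' @param origins Optional [call_origin()] table used to fill node origin
#'   attributes.
#' @return Invisibly, the paths written, or `NULL` (with a warning) for an
#'   empty subnetwork.
#' @export
export_cytoscape <- function(sub, dir, origins = NULL) {
  stopifnot(inherits(sub, "predictive_subnetwork"))
  if (sub$empty || nrow(sub$edges) == 0) {
    warning("empty subnetwork: nothing to export")
    return(invisible(NULL))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  e <- sub$edges
  kw <- ifelse(e$sign == -1L, "represses", "binds")
  sif <- file.path(dir, "subnetwork.sif")
  writeLines(sprintf("%s\t%s\t%s", e$node1, kw, e$node2), sif)

  nodes <- sub$nodes
  nodes$origin <- ""
  if (!is.null(origins)) {
    m <- match(nodes$node, origins$gene)
    nodes$origin <- ifelse(is.na(m), "", origins$origin[m])
  }
  nattr <- file.path(dir, "node_attributes.tsv")
  write_tsv(nodes, nattr)
  eattr <- file.path(dir, "edge_attributes.tsv")
  write_tsv(e, eattr)
  invisible(c(sif = sif, node_attributes = nattr, edge_attributes = eattr))
}
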