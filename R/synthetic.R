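#' Configuration for the synthetic two-group dual-omics cohort
#'
#' Defines the full generative recipe for a cohort emulating a lean
#' insulin-sensitive (LIS) versus obese insulin-resistant (OIR) plasma
#' secretome study: group sizes, feature counts, a signed miRNA/protein
#' interaction network, a planted predictive subnetwork in which signal
#' miRNAs fall and their target proteins rise in the OIR-like group, and the
#' raw measurement layers (RT-qPCR plates, peptide tables with missingness).
#'
#' @param n_group1 Samples in group 1 (LIS-like); default 9.
#' @param n_group2 Samples in group 2 (OIR-like); default 8.
#' @param n_mirna Number of miRNA features; default 374.
#' @param n_protein Number of protein features; default 1499.
#' @param n_signal_edges Planted miRNA->protein signal edges; default 20.
#' @param n_ppi_signal Planted co-elevated protein-protein pairs; default 5.
#' @param n_ppi Background protein-protein edges; default 1500.
#' @param delta_mirna Group effect (log2 units) subtracted from signal
#'   miRNAs in group 2; default 2.5.
#' @param delta_protein Group effect (log2 units) added to signal-target
#'   proteins in group 2; default 2.5.
#' @param sigma Residual SD of log2 abundances; default 1.
#' @param peptide_per_protein Mean extra peptides per protein; each protein
#'   yields `Poisson(peptide_per_protein) + 1` peptides; default 3.
#' @param missing_rate Per-cell missingness probability for peptides in
#'   \[0, 1); default 0.1.
#' @param missing_mechanism `"mcar"` (default, missing completely at random)
#'   or `"intensity"` (lower-intensity peptides more likely missing).
#' @param random_effect_sd SD of an optional subject-level random shift
#'   applied to all features of a sample; default 0 (off).
#' @param degree_alpha,degree_max Truncated power-law parameters for the
#'   miRNA out-degree distribution (P(d) proportional to d^-alpha,
#'   d = 1..degree_max).
#' @param seed Integer RNG seed; all layers are deterministic given the
#'   config.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_group1 = 9, n_group2 = 8,
                             n_mirna = 374, n_protein = 1499,
                             n_signal_edges = 20, n_ppi_signal = 5,
                             n_ppi = 1500,
                             delta_mirna = 2.5, delta_protein = 2.5,
                             sigma = 1,
                             peptide_per_protein = 3,
                             missing_rate = 0.1,
                             missing_mechanism = c("mcar", "intensity"),
                             random_effect_sd = 0,
                             degree_alpha = 2, degree_max = 50,
                             seed = 42L) {
  cfg <- list(n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
              n_mirna = as.integer(n_mirna), n_protein = as.integer(n_protein),
              n_signal_edges = as.integer(n_signal_edges),
              n_ppi_signal = as.integer(n_ppi_signal),
              n_ppi = as.integer(n_ppi),
              delta_mirna = delta_mirna, delta_protein = delta_protein,
              sigma = sigma,
              peptide_per_protein = peptide_per_protein,
              missing_rate = missing_rate,
              missing_mechanism = match.arg(missing_mechanism),
              random_effect_sd = random_effect_sd,
              degree_alpha = degree_alpha,
              degree_max = as.integer(degree_max),
              seed = as.integer(seed))
  counts <- c("n_group1", "n_group2", "n_mirna", "n_protein")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(sprintf("`%s` must be a count >= 1", f))
  for (f in c("n_signal_edges", "n_ppi_signal", "n_ppi"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop(sprintf("`%s` must be a count >= 0", f))
  if (cfg$sigma <= 0) stop("`sigma` must be > 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("`missing_rate` must be in [0, 1)")
  if (cfg$peptide_per_protein < 0)
    stop("`peptide_per_protein` must be >= 0")
  if (cfg$n_signal_edges > cfg$n_mirna)
    stop("cannot plant more signal edges than miRNAs")
  if (cfg$n_signal_edges + 2L * cfg$n_ppi_signal > cfg$n_protein)
    stop("cannot reserve more signal proteins than proteins")
  class(cfg) <- "synthetic_config"
  cfg
}

mirna_ids <- function(n) sprintf("miR-%d", seq_len(n))
protein_ids <- function(n) sprintf("PROT%04d", seq_len(n))

#' Generate a fixture signed interaction network
#'
#' Builds a bipartite miRNA->protein map with a truncated power-law
#' out-degree distribution (many miRNAs with few targets, a few hubs,
#' mimicking sequence-based target prediction maps) plus random
#' protein-protein interaction edges.  Planted signal edges — the ground
#' truth that `generate_cohort()` animates — use reserved miRNAs and
#' proteins that carry no other edges, so each planted edge represents an
#' independent regulatory relation; they are flagged in the `planted`
#' column.
#'
#' @param config A [synthetic_config()].
#' @return A [signed_network()] whose `edges` carry a logical `planted`
#'   column.
#' @export
generate_networks <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mir <- mirna_ids(config$n_mirna)
  prot <- protein_ids(config$n_protein)
  n_sig <- config$n_signal_edges
  n_ppi_sig <- config$n_ppi_signal

  withr::with_seed(config$seed + 1L, {
    sig_mir <- if (n_sig > 0) sample(mir, n_sig) else character(0)
    sig_prot <- if (n_sig > 0) sample(prot, n_sig) else character(0)
    rest_prot <- setdiff(prot, sig_prot)
    ppi_sig_prot <- if (n_ppi_sig > 0) sample(rest_prot, 2L * n_ppi_sig)
                    else character(0)
    bg_mir <- setdiff(mir, sig_mir)
    bg_prot <- setdiff(prot, c(sig_prot, ppi_sig_prot))

    # background miRNA->target edges, truncated power-law out-degree
    dmax <- min(config$degree_max, length(bg_prot))
    dprob <- seq_len(dmax)^(-config$degree_alpha)
    deg <- sample.int(dmax, length(bg_mir), replace = TRUE, prob = dprob)
    neg_bg <- data.frame(
      node1 = rep(bg_mir, deg),
      node2 = unlist(lapply(deg, function(d) sample(bg_prot, d))),
      sign = -1L, planted = FALSE)

    # background PPIs among non-reserved proteins, deduplicated
    ppi_bg <- NULL
    if (config$n_ppi > 0 && length(bg_prot) >= 2) {
      draw <- matrix(replicate(ceiling(config$n_ppi * 1.3) + 10,
                               sample(bg_prot, 2)), nrow = 2)
      key <- paste(pmin(draw[1, ], draw[2, ]), pmax(draw[1, ], draw[2, ]))
      keep <- !duplicated(key)
      draw <- draw[, keep, drop = FALSE]
      draw <- draw[, seq_len(min(config$n_ppi, ncol(draw))), drop = FALSE]
      ppi_bg <- data.frame(node1 = draw[1, ], node2 = draw[2, ],
                           sign = 1L, planted = FALSE)
    }

    planted_neg <- if (n_sig > 0)
      data.frame(node1 = sig_mir, node2 = sig_prot, sign = -1L, planted = TRUE)
    planted_pos <- if (n_ppi_sig > 0)
      data.frame(node1 = ppi_sig_prot[seq_len(n_ppi_sig)],
                 node2 = ppi_sig_prot[n_ppi_sig + seq_len(n_ppi_sig)],
                 sign = 1L, planted = TRUE)

    edges <- rbind(planted_neg, neg_bg, ppi_bg, planted_pos)
  })

  node_type <- c(stats::setNames(rep("mirna", length(mir)), mir),
                 stats::setNames(rep("protein", length(prot)), prot))
  net <- signed_network(edges, node_type)
  n_neg <- sum(net$edges$sign == -1L)
  if (config$n_signal_edges > n_neg)
    stop("config requests more signal edges than generated miRNA->protein edges")
  net
}

#' Generate a two-group dual-omics cohort with planted network signal
#'
#' Draws log2 abundances as feature baseline + group effect + Gaussian
#' noise.  For every planted miRNA->protein edge the miRNA is shifted by
#' `-delta_mirna` and its target protein by `+delta_protein` in group 2
#' (the OIR-like group: reduced miRNA secretion, elevated target protein
#' secretion); for planted PPI pairs both proteins are shifted by
#' `+delta_protein`.  All other features have zero group effect.
#'
#' @param config A [synthetic_config()].
#' @param network A [generate_networks()] result carrying `planted` flags.
#' @return List with elements `mirna` and `protein`
#'   ([abundance_matrix()] objects, log2 scale) and `truth` (list with
#'   `signal_edges`, `signal_features`, `config_seed`).
#' @export
generate_cohort <- function(config, network) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(network, "signed_network"))
  if (is.null(network$edges$planted))
    stop("network does not carry planted-edge flags; use generate_networks()")
  mir <- mirna_ids(config$n_mirna)
  prot <- protein_ids(config$n_protein)
  net_mir <- names(network$node_type)[network$node_type == "mirna"]
  net_prot <- names(network$node_type)[network$node_type == "protein"]
  if (!all(net_mir %in% mir) || !all(net_prot %in% prot))
    stop("the cohort's feature identifiers do not cover the network nodes")

  samples <- c(sprintf("LIS%d", seq_len(config$n_group1)),
               sprintf("OIR%d", seq_len(config$n_group2)))
  groups <- factor(rep(c("LIS", "OIR"), c(config$n_group1, config$n_group2)),
                   levels = c("LIS", "OIR"))
  n <- length(samples)

  pl <- network$edges[network$edges$planted, , drop = FALSE]
  pl_neg <- pl[pl$sign == -1L, , drop = FALSE]
  pl_pos <- pl[pl$sign == 1L, , drop = FALSE]

  eff_mir <- stats::setNames(numeric(length(mir)), mir)
  eff_prot <- stats::setNames(numeric(length(prot)), prot)
  eff_mir[pl_neg$node1] <- -config$delta_mirna
  eff_prot[pl_neg$node2] <- eff_prot[pl_neg$node2] + config$delta_protein
  eff_prot[pl_pos$node1] <- eff_prot[pl_pos$node1] + config$delta_protein
  eff_prot[pl_pos$node2] <- eff_prot[pl_pos$node2] + config$delta_protein

  withr::with_seed(config$seed + 2L, {
    mu_m <- stats::rnorm(length(mir), mean = 14, sd = 3)
    mu_p <- stats::rnorm(length(prot), mean = 20, sd = 2)
    subj <- if (config$random_effect_sd > 0)
      stats::rnorm(n, 0, config$random_effect_sd) else numeric(n)
    oir <- as.numeric(groups == "OIR")
    xm <- outer(mu_m, rep(1, n)) + outer(eff_mir, oir) +
      matrix(stats::rnorm(length(mir) * n, 0, config$sigma),
             length(mir), n) +
      outer(rep(1, length(mir)), subj)
    xp <- outer(mu_p, rep(1, n)) + outer(eff_prot, oir) +
      matrix(stats::rnorm(length(prot) * n, 0, config$sigma),
             length(prot), n) +
      outer(rep(1, length(prot)), subj)
  })
  dimnames(xm) <- list(mir, samples)
  dimnames(xp) <- list(prot, samples)

  truth <- list(
    signal_edges = pl$edge_id,
    signal_features = data.frame(
      feature = c(names(eff_mir)[eff_mir != 0], names(eff_prot)[eff_prot != 0]),
      omics = rep(c("mirna", "protein"),
                  c(sum(eff_mir != 0), sum(eff_prot != 0))),
      effect = c(eff_mir[eff_mir != 0], eff_prot[eff_prot != 0]),
      row.names = NULL),
    config_seed = config$seed)

  list(mirna = abundance_matrix(xm, groups, "mirna"),
       protein = abundance_matrix(xp, groups, "protein"),
       truth = truth)
}

#' Split protein intensities into a peptide-level table with missing values
#'
#' Each protein is observed through `Poisson(peptide_per_protein) + 1`
#' peptides whose fixed ionization-efficiency weights sum to one, so the
#' linear-scale peptide intensities sum exactly to the protein intensity
#' before missingness.  Cells are then masked missing at `missing_rate`
#' (completely at random by default; an intensity-dependent mechanism is
#' available for robustness checks).
#'
#' @param truth_protein Protein [abundance_matrix()] (log2 scale).
#' @param config A [synthetic_config()].
#' @return A [peptide_matrix()] (linear scale, `NA` = missing).
#' @export
generate_peptide_table <- function(truth_protein, config) {
  stopifnot(inherits(truth_protein, "abundance_matrix"),
            inherits(config, "synthetic_config"))
  lin <- 2^truth_protein$values
  prot <- rownames(lin)
  withr::with_seed(config$seed + 4L, {
    n_pep <- stats::rpois(length(prot), config$peptide_per_protein) + 1L
    pep_protein <- rep(prot, n_pep)
    pep_ids <- sprintf("%s_pep%d", pep_protein,
                       unlist(lapply(n_pep, seq_len)))
    w <- stats::rgamma(length(pep_ids), shape = 2, rate = 1)
    wsplit <- split(w, rep(seq_along(prot), n_pep))
    w <- unlist(lapply(wsplit, function(v) v / sum(v)), use.names = FALSE)
    pep <- lin[pep_protein, , drop = FALSE] * w
    rownames(pep) <- pep_ids
    if (config$missing_rate > 0) {
      if (config$missing_mechanism == "mcar") {
        mask <- matrix(stats::runif(length(pep)) < config$missing_rate,
                       nrow(pep), ncol(pep))
      } else {
        # intensity-dependent: logistic in rank of log intensity, calibrated
        # so the marginal rate equals missing_rate
        r <- rank(-log2(pep)) / length(pep)
        pr <- config$missing_rate * 2 * r
        mask <- matrix(stats::runif(length(pep)) < pr, nrow(pep), ncol(pep))
      }
      pep[mask] <- NA_real_
    }
  })
  peptide_matrix(pep,
                 data.frame(peptide = pep_ids, protein = pep_protein),
                 truth_protein$groups)
}

#' Generate tissue annotations and gene-set fixtures
#'
#' Emits a gene-by-tissue evidence table in the style of proteome-atlas
#' exports (separate mRNA-level and protein-level flags over a fixed
#' vocabulary of metabolic tissues) and a GMT-style gene-set collection.
#' Proteins targeted by planted signal edges are biased towards adipose and
#' liver evidence, and one constructed set (`SIGNAL_PATHWAY`) consists
#' mostly of planted signal proteins so downstream enrichment has a known
#' positive.
#'
#' @param network A [generate_networks()] result.
#' @param config A [synthetic_config()].
#' @return List with `tissue` (data.frame gene/tissue/rna_evidence/
#'   protein_evidence) and `gene_sets` (named list of character vectors).
#' @export
generate_annotations <- function(network, config) {
  stopifnot(inherits(network, "signed_network"),
            inherits(config, "synthetic_config"))
  tissues <- c("adipose", "liver", "skeletal muscle", "kidney", "pancreas",
               "heart", "intestine")
  prot <- names(network$node_type)[network$node_type == "protein"]
  pl <- network$edges[network$edges$planted, , drop = FALSE]
  sig_prot <- unique(c(pl$node2[pl$sign == -1L],
                       pl$node1[pl$sign == 1L], pl$node2[pl$sign == 1L]))

  withr::with_seed(config$seed + 5L, {
    rows <- lapply(prot, function(g) {
      if (g %in% sig_prot) {
        origin <- sample(c("adipose", "liver"), 1)
        extra <- sample(setdiff(tissues, origin),
                        stats::rbinom(1, 2, 0.3))
        rna_in <- unique(c(origin, extra,
                           sample(tissues, stats::rbinom(1, 2, 0.3))))
        prot_in <- unique(c(origin, extra))
      } else {
        rna_in <- sample(tissues, 1 + stats::rbinom(1, length(tissues) - 1, 0.25))
        prot_in <- sample(rna_in, max(1, round(length(rna_in) * 0.7)))
        prot_in <- unique(c(prot_in,
                            sample(tissues, stats::rbinom(1, 1, 0.1))))
      }
      data.frame(gene = g, tissue = tissues,
                 rna_evidence = tissues %in% rna_in,
                 protein_evidence = tissues %in% prot_in)
    })
    tissue <- do.call(rbind, rows)

    # gene sets: one planted signal pathway (>= 80% signal proteins) plus
    # random background sets
    n_decoy <- max(0L, floor(length(sig_prot) / 5))
    signal_set <- c(sig_prot, sample(setdiff(prot, sig_prot), n_decoy))
    gene_sets <- c(list(SIGNAL_PATHWAY = signal_set),
                   stats::setNames(
                     lapply(1:10, function(i)
                       sample(setdiff(prot, sig_prot),
                              min(30, length(prot) - length(sig_prot)))),
                     sprintf("RANDOM_SET_%02d", 1:10)))
  })
  rownames(tissue) <- NULL
  list(tissue = tissue, gene_sets = gene_sets)
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = fasting insulin (mU/l) x fasting glucose (mmol/l) / 22.5`.
#'
#' @param insulin Fasting insulin in mU/l (> 0); vectorized.
#' @param glucose Fasting glucose in mmol/l (> 0); vectorized.
#' @return Unitless HOMA-IR score(s).
#' @examples
#' homa_ir(4.31, 4.33)  # 0.829..., the lean insulin-sensitive group mean
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(!is.finite(insulin)) || any(!is.finite(glucose)) ||
      any(insulin <= 0) || any(glucose <= 0))
    stop("insulin and glucose must be positive and finite")
  insulin * glucose / 22.5
}

#' Generate per-subject clinical records
#'
#' Draws fasting insulin and glucose per subject around group-typical means
#' (low insulin in the lean insulin-sensitive group, high in the obese
#' insulin-resistant group) and computes HOMA-IR exactly from the
#' per-subject values.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `subject_id`, `group`,
#'   `fasting_insulin`, `fasting_glucose`, `homa_ir`.
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n1 <- config$n_group1; n2 <- config$n_group2
  withr::with_seed(config$seed + 6L, {
    ins <- c(truncnorm_pos(n1, 4.31, 1.5), truncnorm_pos(n2, 21.9, 6.5))
    glu <- c(truncnorm_pos(n1, 4.33, 0.2), truncnorm_pos(n2, 4.71, 0.4))
  })
  data.frame(
    subject_id = c(sprintf("LIS%d", seq_len(n1)), sprintf("OIR%d", seq_len(n2))),
    group = rep(c("LIS", "OIR"), c(n1, n2)),
    fasting_insulin = ins,
    fasting_glucose = glu,
    homa_ir = homa_ir(ins, glu))
}

# Normal draw truncated to positive values by rejection
truncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}
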