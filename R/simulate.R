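#' Configuration for the synthetic study generator
#'
#' Describes a synthetic cohort emulating the study design: three donor
#' groups (24 healthy donors, 23 pSS and 25 SLE patients by default), four
#' sorted cell types, and three culture conditions (steady-state sorting,
#' 18 h anti-CD3 stimulation, 18 h PBS control). Expression is generated on
#' the FPKM scale from log-normal gene/donor baselines with planted effects,
#' then converted to integer counts through gene-length and depth scaling
#' followed by Poisson sampling, which makes FPKM normalization exactly
#' invertible in expectation.
#'
#' Planted structure (all gene blocks mutually disjoint):
#' * a shared inflammatory stimulation program in all aCD3 samples,
#' * group-specific differential genes added on top of the stimulation
#'   response (recovered by the two-step relative-expression contrast),
#' * an interferon-response set whose steady-state shift scales with the
#'   donor's disease-activity class (`activity_effect`),
#' * genes co-expressed with the first interferon gene at correlation
#'   `coexpr_rho` (guilt-by-association targets),
#' * co-regulated gene modules with distinct cell-type profiles separated by
#'   `module_sep` noise SDs (k-means targets),
#' * cell-type marker sets (signature QC targets),
#' * ligand-receptor events switched on per donor with group-specific
#'   probabilities (cell-cell communication targets).
#'
#' @param n_genes number of genes in the universe.
#' @param group_sizes named integer vector of donors per group.
#' @param cell_types,conditions factor levels of the design.
#' @param n_deg planted differential genes per disease contrast.
#' @param deg_log2fc planted effect size, log2 FPKM ratio.
#' @param n_stim_genes,stim_log2fc shared stimulation program (half up, half
#'   down) applied to every aCD3 sample.
#' @param ifn_set_size number of planted interferon-response genes.
#' @param activity_effect named numeric, log2 FPKM shift of the interferon
#'   set in steady-state patient samples per activity class
#'   (Low/Moderate/High).
#' @param n_modules,module_sizes,module_sep planted co-regulated modules;
#'   separation is in units of the noise SD `dispersion`.
#' @param n_coexpr,coexpr_rho genes co-expressed with the first interferon
#'   gene at the given correlation.
#' @param coexpr_scope named list restricting where the co-expression holds
#'   (`group`, `cell_type`, `condition`, `activity_class`; `NULL` entries
#'   match everything). Guilt-by-association contrasts a condition against
#'   the pool of all conditions, so a detectable planted signal must be
#'   condition-specific; the default scopes it to steady-state Th samples of
#'   SLE donors.
#' @param lr_pairs data.frame of planted ligand-receptor events with columns
#'   `sender`, `receiver`, `ligand`, `receptor`, `category`, `p_HD`, `p_pSS`,
#'   `p_SLE` (per-donor activation probabilities).
#' @param lr_log2fc ligand up-shift in the sender aCD3 sample of an active
#'   donor.
#' @param n_markers,marker_log2fc cell-type marker genes per population.
#' @param dispersion log-normal sigma (natural log) of per-entry noise.
#' @param dropout_rate fraction of FPKM entries forced to zero, in [0,1).
#' @param qc_dropout fraction of whole samples dropped at random, emulating
#'   QC attrition.
#' @param depth_mean mean sequencing depth (fragments per sample).
#' @param activity_max activity scores are drawn uniformly from 0..activity_max
#'   for patient donors (healthy donors carry no score).
#' @param seed integer; fully determines the output.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 2000,
                              group_sizes = c(HD = 24, pSS = 23, SLE = 25),
                              cell_types = c("Th", "CTL", "NK", "B"),
                              conditions = c("steady", "aCD3", "PBS"),
                              n_deg = 100,
                              deg_log2fc = 1.5,
                              n_stim_genes = 150,
                              stim_log2fc = 2,
                              ifn_set_size = 50,
                              activity_effect = c(Low = 0.5, Moderate = 1.0,
                                                  High = 2.0),
                              n_modules = 3,
                              module_sizes = c(80, 60, 40),
                              module_sep = 3,
                              n_coexpr = 20,
                              coexpr_rho = 0.9,
                              coexpr_scope = list(group = "SLE",
                                                  cell_type = "Th",
                                                  condition = "steady",
                                                  activity_class = NULL),
                              lr_pairs = default_lr_events(),
                              lr_log2fc = 4,
                              n_markers = 30,
                              marker_log2fc = 2,
                              dispersion = 0.3,
                              dropout_rate = 0,
                              qc_dropout = 0.05,
                              depth_mean = 5e6,
                              activity_max = 14,
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
              cell_types = cell_types, conditions = conditions,
              n_deg = as.integer(n_deg), deg_log2fc = deg_log2fc,
              n_stim_genes = as.integer(n_stim_genes),
              stim_log2fc = stim_log2fc,
              ifn_set_size = as.integer(ifn_set_size),
              activity_effect = activity_effect,
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              module_sep = module_sep,
              n_coexpr = as.integer(n_coexpr), coexpr_rho = coexpr_rho,
              coexpr_scope = coexpr_scope,
              lr_pairs = lr_pairs, lr_log2fc = lr_log2fc,
              n_markers = as.integer(n_markers),
              marker_log2fc = marker_log2fc,
              dispersion = dispersion, dropout_rate = dropout_rate,
              qc_dropout = qc_dropout, depth_mean = depth_mean,
              activity_max = as.integer(activity_max),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

#' Default planted ligand-receptor events
#'
#' Two events detected in most disease donors but few healthy donors,
#' mirroring the kind of group-shifted occurrence the communication analysis
#' is designed to pick up.
#' @return data.frame of planted events.
#' @export
default_lr_events <- function() {
  data.frame(sender = c("Th", "CTL"),
             receiver = c("B", "NK"),
             ligand = c("LIGSYN01", "LIGSYN02"),
             receptor = c("RECSYN01", "RECSYN02"),
             category = c("Cytokines", "chemokines"),
             p_HD = c(0.3, 0.3), p_pSS = c(0.9, 0.9), p_SLE = c(0.9, 0.9),
             stringsAsFactors = FALSE)
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, all(cfg$group_sizes > 0),
            length(cfg$cell_types) >= 1, length(cfg$conditions) >= 1)
  if (!all(c("HD") %in% names(cfg$group_sizes)))
    stop("group_sizes must include an 'HD' group")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (cfg$qc_dropout < 0 || cfg$qc_dropout >= 1)
    stop("qc_dropout must lie in [0, 1)")
  if (!is.finite(cfg$deg_log2fc)) stop("deg_log2fc must be finite")
  if (length(cfg$module_sizes) != cfg$n_modules)
    stop("module_sizes must have length n_modules")
  if (!all(c("Low", "Moderate", "High") %in% names(cfg$activity_effect)))
    stop("activity_effect must name Low, Moderate and High")
  n_contrasts <- sum(names(cfg$group_sizes) != "HD")
  n_lr_genes <- 2L * nrow(cfg$lr_pairs)
  planted <- cfg$ifn_set_size + cfg$n_stim_genes +
    n_contrasts * cfg$n_deg + sum(cfg$module_sizes) + cfg$n_coexpr +
    cfg$n_markers * length(cfg$cell_types) + n_lr_genes
  if (planted > cfg$n_genes)
    stop("inconsistent config: planted gene blocks (", planted,
         ") exceed n_genes (", cfg$n_genes, ")")
  invisible(cfg)
}

#' Simulate a full synthetic study
#'
#' Generates one sample per (donor, cell type, condition), drops a random
#' `qc_dropout` fraction of whole samples, and returns raw integer counts
#' together with gene lengths, sample metadata and a `TruthSet` recording all
#' planted structure (including the latent expected FPKM matrix, used by
#' recovery tests).
#'
#' @param config a `SimulationConfig`.
#' @return list with elements `counts` (`ExpressionMatrix`, raw_counts layer),
#'   `gene_lengths` (named numeric, bp), `samples` (`SampleTable`) and
#'   `truth` (`TruthSet`).
#' @export
simulate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  log2e <- log(2)  # planted effects are stated in log2; model is natural log

  ## ---- gene universe and planted blocks -------------------------------
  n <- config$n_genes
  groups <- names(config$group_sizes)
  diseases <- setdiff(groups, "HD")
  idx <- 0L
  take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
  ifn_idx <- take(config$ifn_set_size)
  stim_idx <- take(config$n_stim_genes)
  deg_idx <- lapply(diseases, function(g) take(config$n_deg))
  names(deg_idx) <- diseases
  module_idx <- lapply(config$module_sizes, take)
  coexpr_idx <- take(config$n_coexpr)
  marker_idx <- lapply(config$cell_types, function(ct) take(config$n_markers))
  names(marker_idx) <- config$cell_types
  n_lr <- nrow(config$lr_pairs)
  lig_idx <- if (n_lr) take(n_lr) else integer()
  rec_idx <- if (n_lr) take(n_lr) else integer()

  gene_ids <- sprintf("GENE%04d", seq_len(n))
  gene_ids[ifn_idx] <- sprintf("IFNSYN%03d", seq_along(ifn_idx))
  if (n_lr) {
    gene_ids[lig_idx] <- config$lr_pairs$ligand
    gene_ids[rec_idx] <- config$lr_pairs$receptor
  }

  ## ---- design ----------------------------------------------------------
  donors <- unlist(lapply(groups, function(g)
    sprintf("%s%02d", g, seq_len(config$group_sizes[[g]]))))
  donor_group <- rep(groups, config$group_sizes)
  names(donor_group) <- donors

  activity_scores <- stats::setNames(rep(NA_integer_, length(donors)), donors)
  patient <- donor_group != "HD"
  activity_scores[patient] <- sample.int(config$activity_max + 1L,
                                         sum(patient), replace = TRUE) - 1L
  activity_class <- vapply(activity_scores, function(s)
    if (is.na(s)) NA_character_ else classify_activity(s)$class, character(1))

  design <- expand.grid(condition = config$conditions,
                        cell_type = config$cell_types,
                        donor_id = donors,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("donor_id", "cell_type", "condition")]
  design$group <- donor_group[design$donor_id]
  design$sample_id <- paste(design$donor_id, design$cell_type,
                            design$condition, sep = "_")
  n_samp <- nrow(design)

  ## ---- latent log-FPKM -------------------------------------------------
  mu_gene <- stats::rnorm(n, mean = log(5), sd = 1.2)
  # planted structure lives on robustly expressed genes (>= ~3 FPKM): the
  # study's analyses operate on the expressed subset, and truth planted on
  # near-zero-FPKM genes would be unmeasurable by construction
  planted_idx <- c(ifn_idx, stim_idx, unlist(deg_idx), unlist(module_idx),
                   coexpr_idx, unlist(marker_idx), lig_idx)
  mu_gene[planted_idx] <- log(3) +
    abs(stats::rnorm(length(planted_idx), 0, 0.8))
  mu_gene[rec_idx] <- log(20)            # receptors constitutively expressed
  donor_eff <- stats::setNames(stats::rnorm(length(donors), 0, 0.25), donors)

  logfpkm <- matrix(mu_gene, nrow = n, ncol = n_samp)
  logfpkm <- sweep(logfpkm, 2, donor_eff[design$donor_id], `+`)

  # cell-type markers: up in their own population, every condition
  for (ct in config$cell_types) {
    cols <- design$cell_type == ct
    logfpkm[marker_idx[[ct]], cols] <-
      logfpkm[marker_idx[[ct]], cols] + config$marker_log2fc * log2e
  }

  # shared stimulation program in all aCD3 samples (half up, half down)
  stim_sign <- rep(c(1, -1), length.out = length(stim_idx))
  acd3 <- design$condition == "aCD3"
  if (any(acd3) && length(stim_idx))
    logfpkm[stim_idx, acd3] <- logfpkm[stim_idx, acd3] +
      stim_sign * config$stim_log2fc * log2e

  # group-specific DEGs on top of the stimulation response
  deg_sign <- rep(c(1, -1), length.out = config$n_deg)
  for (g in diseases) {
    cols <- acd3 & design$group == g
    if (any(cols) && config$n_deg)
      logfpkm[deg_idx[[g]], cols] <- logfpkm[deg_idx[[g]], cols] +
        deg_sign * config$deg_log2fc * log2e
  }

  # interferon program at steady-state, scaled by activity class
  steady <- design$condition == "steady"
  act_shift <- rep(0, n_samp)
  cls <- activity_class[design$donor_id]
  sel <- steady & !is.na(cls)
  act_shift[sel] <- config$activity_effect[cls[sel]] * log2e
  ifn_target <- c(ifn_idx, coexpr_idx)   # co-expressed genes track the program
  if (length(ifn_target))
    logfpkm[ifn_target, ] <- sweep(logfpkm[ifn_target, , drop = FALSE], 2,
                                   act_shift, `+`)

  # co-regulated modules: orthogonal cell-type profiles, one module up (or
  # down, on the second pass through the cell types) in exactly one
  # population, shifted by module_sep noise SDs
  n_ct <- length(config$cell_types)
  for (m in seq_len(config$n_modules)) {
    prof <- stats::setNames(rep(0, n_ct), config$cell_types)
    ct_slot <- ((m - 1) %% n_ct) + 1
    prof[ct_slot] <- config$module_sep * config$dispersion *
      (-1)^((m - 1) %/% n_ct)
    logfpkm[module_idx[[m]], ] <-
      sweep(logfpkm[module_idx[[m]], , drop = FALSE], 2,
            prof[design$cell_type], `+`)
  }

  # ligand-receptor events: per-donor Bernoulli activation
  lr_act <- NULL
  if (n_lr) {
    lr_act <- matrix(FALSE, n_lr, length(donors),
                     dimnames = list(NULL, donors))
    for (e in seq_len(n_lr)) {
      p <- unlist(config$lr_pairs[e, paste0("p_", donor_group)])
      lr_act[e, ] <- stats::runif(length(donors)) < p
      on <- donors[lr_act[e, ]]
      cols <- acd3 & design$cell_type == config$lr_pairs$sender[e] &
        design$donor_id %in% on
      logfpkm[lig_idx[e], cols] <- logfpkm[lig_idx[e], cols] +
        config$lr_log2fc * log2e
    }
  }

  # noise; co-expressed genes share the first interferon gene's noise, but
  # only inside the configured scope (condition-specific co-expression)
  eps <- matrix(stats::rnorm(n * n_samp, 0, config$dispersion), n, n_samp)
  if (config$n_coexpr > 0 && length(ifn_idx)) {
    scope <- rep(TRUE, n_samp)
    sc <- config$coexpr_scope
    if (!is.null(sc$group)) scope <- scope & design$group %in% sc$group
    if (!is.null(sc$cell_type))
      scope <- scope & design$cell_type %in% sc$cell_type
    if (!is.null(sc$condition))
      scope <- scope & design$condition %in% sc$condition
    if (!is.null(sc$activity_class))
      scope <- scope & !is.na(cls) & cls %in% sc$activity_class
    rho <- config$coexpr_rho
    eps[coexpr_idx, scope] <-
      rho * matrix(eps[ifn_idx[1], scope], config$n_coexpr, sum(scope),
                   byrow = TRUE) +
      sqrt(1 - rho^2) * eps[coexpr_idx, scope, drop = FALSE]
    # tie baselines so Euclidean distance to the partner gene is small
    logfpkm[coexpr_idx, ] <- logfpkm[coexpr_idx, ] -
      mu_gene[coexpr_idx] + mu_gene[ifn_idx[1]] +
      stats::rnorm(config$n_coexpr, 0, 0.05)
  }
  logfpkm <- logfpkm + eps

  expected_fpkm <- exp(logfpkm)
  if (config$dropout_rate > 0) {
    drop <- stats::runif(length(expected_fpkm)) < config$dropout_rate
    expected_fpkm[drop] <- 0
  }

  ## ---- counts ----------------------------------------------------------
  gene_lengths <- pmax(200, round(exp(stats::rnorm(n, log(1500), 0.5))))
  names(gene_lengths) <- gene_ids
  # enforce the FPKM identity sum(FPKM * len_kb) = 1e6 per sample, so the
  # FPKM transform is exactly invertible (recovered FPKM ~ latent up to
  # Poisson noise) and counts carry realistic per-gene depth; the per-sample
  # factor also reproduces FPKM's compositional behavior (e.g. the
  # stimulation program's mass deflates every other gene's FPKM)
  mass <- colSums(expected_fpkm * (gene_lengths / 1000))
  expected_fpkm <- sweep(expected_fpkm, 2, 1e6 / mass, `*`)
  depth <- round(exp(stats::rnorm(n_samp, log(config$depth_mean), 0.15)))
  lambda <- expected_fpkm * (gene_lengths / 1000) %o% (depth / 1e6)
  counts <- matrix(stats::rpois(length(lambda), lambda), n, n_samp,
                   dimnames = list(gene_ids, design$sample_id))

  ## ---- QC attrition ----------------------------------------------------
  n_drop <- floor(config$qc_dropout * n_samp)
  dropped <- if (n_drop > 0) sort(sample(design$sample_id, n_drop)) else
    character()
  keep <- !(design$sample_id %in% dropped)

  st <- sample_table(data.frame(
    sample_id = design$sample_id, donor_id = design$donor_id,
    group = design$group, cell_type = design$cell_type,
    condition = design$condition,
    activity_score = unname(activity_scores[design$donor_id]),
    activity_class = unname(activity_class[design$donor_id]),
    stringsAsFactors = FALSE)[keep, , drop = FALSE])
  rownames(st) <- NULL

  dimnames(expected_fpkm) <- dimnames(counts)
  truth <- structure(list(
    gene_universe = gene_ids,
    deg_genes = stats::setNames(lapply(diseases, function(g)
      stats::setNames(deg_sign * config$deg_log2fc, gene_ids[deg_idx[[g]]])),
      sprintf("HD-vs-%s|aCD3", diseases)),
    stim_genes = stats::setNames(stim_sign * config$stim_log2fc,
                                 gene_ids[stim_idx]),
    ifn_genes = gene_ids[ifn_idx],
    coexpr_genes = stats::setNames(
      rep(if (length(ifn_idx)) gene_ids[ifn_idx[1]] else character(0),
          config$n_coexpr), gene_ids[coexpr_idx]),
    coexpr_scope = config$coexpr_scope,
    module_assignment = stats::setNames(
      rep(seq_len(config$n_modules), config$module_sizes),
      gene_ids[unlist(module_idx)]),
    marker_genes = lapply(marker_idx, function(i) gene_ids[i]),
    lr_events = config$lr_pairs,
    lr_activations = lr_act,
    activity_scores = activity_scores,
    expected_fpkm = expected_fpkm[, keep, drop = FALSE],
    dropped_samples = dropped), class = "TruthSet")

  list(counts = expression_matrix(counts[, keep, drop = FALSE], "raw_counts",
                                  provenance = sprintf("simulate(seed=%d)",
                                                       config$seed)),
       gene_lengths = gene_lengths,
       samples = st,
       truth = truth)
}

#' @export
print.TruthSet <- function(x, ...) {
  cat(sprintf(paste0("TruthSet: %d genes | %d IFN | %d coexpr | %d modules",
                     " | %d LR events | %d DEG contrasts\n"),
              length(x$gene_universe), length(x$ifn_genes),
              length(x$coexpr_genes),
              length(unique(x$module_assignment)),
              if (is.null(x$lr_events)) 0L else nrow(x$lr_events),
              length(x$deg_genes)))
  invisible(x)
}

#' Synthetic gene-set catalog around a TruthSet
#'
#' Stands in for a curated pathway collection: contains one set equal to the
#' planted interferon genes (`IFN_TYPE_I_SYNTH`), one set per planted module
#' (`MODULE_<m>_SYNTH`), plus `n_decoy_sets` random decoy sets with sizes
#' drawn from `size_range`.
#'
#' @param truth a `TruthSet`.
#' @param n_decoy_sets number of random decoy sets.
#' @param size_range integer pair, inclusive bounds for decoy sizes.
#' @param seed integer seed.
#' @return a `GeneSetCatalog`.
#' @export
simulate_genesets <- function(truth, n_decoy_sets = 50,
                              size_range = c(10, 100), seed = 1) {
  if (size_range[1] < 1 || size_range[2] > length(truth$gene_universe))
    stop("invalid range: size_range must lie within [1, n_genes]")
  set.seed(seed)
  sets <- list(IFN_TYPE_I_SYNTH = truth$ifn_genes)
  for (m in sort(unique(truth$module_assignment)))
    sets[[sprintf("MODULE_%d_SYNTH", m)]] <-
      names(truth$module_assignment)[truth$module_assignment == m]
  if (n_decoy_sets > 0) {
    sizes <- size_range[1] - 1L +
      sample.int(size_range[2] - size_range[1] + 1L, n_decoy_sets,
                 replace = TRUE)
    for (d in seq_len(n_decoy_sets))
      sets[[sprintf("DECOY_%03d", d)]] <- sample(truth$gene_universe, sizes[d])
  }
  gene_set_catalog(sets, provenance = "synthetic")
}

#' Cell-type marker catalog from a TruthSet
#'
#' One marker set per simulated cell type (`MARKERS_<cell type>`), as needed
#' by the signature QC step.
#' @param truth a `TruthSet`.
#' @return a `GeneSetCatalog`.
#' @export
marker_catalog <- function(truth) {
  sets <- truth$marker_genes
  names(sets) <- paste0("MARKERS_", names(sets))
  gene_set_catalog(sets, provenance = "synthetic cell-type markers")
}

#' Synthetic ligand-receptor table
#'
#' All planted events plus `n_decoy_pairs` random gene pairs; every row
#' carries a functional category from the fixed six-label vocabulary.
#'
#' @param truth a `TruthSet`.
#' @param n_decoy_pairs number of decoy pairs.
#' @param seed integer seed.
#' @return an `LRTable` (data.frame with columns ligand, receptor, category).
#' @export
simulate_lr_table <- function(truth, n_decoy_pairs = 20, seed = 1) {
  set.seed(seed)
  planted <- truth$lr_events[, c("ligand", "receptor", "category")]
  if (n_decoy_pairs > 0) {
    pool <- setdiff(truth$gene_universe,
                    c(planted$ligand, planted$receptor))
    pick <- matrix(sample(pool, 2 * n_decoy_pairs), ncol = 2)
    decoy <- data.frame(ligand = pick[, 1], receptor = pick[, 2],
                        category = sample(lr_categories(), n_decoy_pairs,
                                          replace = TRUE),
                        stringsAsFactors = FALSE)
    planted <- rbind(planted, decoy)
  }
  lr_table(planted)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the interchange files consumed by the command-line entry points:
#' `counts.tsv`, `gene_lengths.tsv`, `samples.tsv`, `truth.json`, and — when
#' a catalog / LR table is supplied — `sets.gmt` and `lr_pairs.tsv`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @param catalog optional `GeneSetCatalog` to write as `sets.gmt`.
#' @param lr optional `LRTable` to write as `lr_pairs.tsv`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, catalog = NULL, lr = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(
    data.frame(gene_id = names(sim$gene_lengths),
               length = unname(sim$gene_lengths)),
    file.path(dir, "gene_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(as.data.frame(sim$samples),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$expected_fpkm <- NULL   # latent matrix stays in memory only
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(catalog)) write_gmt(catalog, file.path(dir, "sets.gmt"))
  if (!is.null(lr))
    utils::write.table(lr, file.path(dir, "lr_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
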