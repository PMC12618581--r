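#' Simulation configuration
#'
#' Parameters of the seeded generators that emulate every input the
#' pipeline consumes. Defaults mirror the structure of the multi-species
#' laboratory design (four species, the four mating stages S/P/GZ/A, three
#' replicates per condition, ~500 gene families) and the MAG survey
#' (MAGs x stations x depth). Counts are negative binomial around
#' log-normal baselines (dispersion 0.1, a typical bulk RNA-seq
#' overdispersion; baseline sigma 1.5 in log10 units for a realistic
#' dynamic range).
#'
#' @param n_species number of laboratory species.
#' @param stages mating stages profiled in every species.
#' @param replicates replicates per condition (each sexual stage, and the
#'   vegetative control).
#' @param n_families gene families.
#' @param present_prob probability a background family occurs in a species.
#' @param dup_prob probability a present background family has two copies.
#' @param diatom_specific_prob probability a background family is
#'   diatom-specific.
#' @param n_planted_markers planted sex-marker families (diatom-specific,
#'   single copy, present in all species).
#' @param n_planted_controls planted control families (flat expression,
#'   eligible as matched controls).
#' @param effect_range range of the planted log2 fold change, drawn
#'   uniformly per family.
#' @param stages_affected stages in which planted markers are upregulated.
#' @param baseline_log10cpm_mean,baseline_log10cpm_sd log-normal baseline
#'   expression (log10 CPM) of background families.
#' @param marker_baseline_log10cpm_range planted-marker baseline (log10 CPM)
#'   drawn uniformly in this range.
#' @param dispersion negative-binomial dispersion.
#' @param lib_size expected library size per laboratory sample.
#' @param n_atlas_conditions,atlas_replicates size of the simulated
#'   expression atlas.
#' @param n_mags,n_mag_samples MAG survey dimensions (samples = stations x
#'   two depths).
#' @param genes_per_mag background genes per MAG.
#' @param planted_sexual_frac fraction of retained-size MAG x sample cells
#'   planted as sexual.
#' @param mag_depth_meanlog,mag_depth_sdlog log-normal sequencing depth of a
#'   MAG x sample cell.
#' @param low_depth_frac fraction of cells given a shallow depth (below the
#'   retention filter).
#' @param marker_veg_meanlog,marker_veg_sdlog log-normal vegetative TPM of
#'   marker and control genes (the background-leakage distribution, shared
#'   with the calibration reference so the 95th-percentile threshold has a
#'   designed ~5% per-draw exceedance).
#' @param marker_sex_meanlog,marker_sex_sdlog log-normal TPM of panel
#'   markers in planted sexual cells.
#' @param n_reference_samples,reference_genes_per_family calibration
#'   reference: vegetative samples and member genes per marker family.
#' @param tree_n_refs,tree_n_outgroups,tree_n_inside,tree_n_outside tips of
#'   a simulated marker tree.
#' @param tree_support bootstrap support assigned to internal nodes.
#' @param hit_n_true,hit_n_decoy,hit_true_score,hit_decoy_score,hit_score_sd
#'   simulated HMMER hit table: counts and score distributions (bits).
#' @param rng_seed default seed used when a generator is called without one.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_species = 4,
                       stages = c("S", "P", "GZ", "A"),
                       replicates = 3,
                       n_families = 500,
                       present_prob = 0.85,
                       dup_prob = 0.1,
                       diatom_specific_prob = 0.3,
                       n_planted_markers = 3,
                       n_planted_controls = 2,
                       effect_range = c(3, 6),
                       stages_affected = c("S", "P", "GZ", "A"),
                       baseline_log10cpm_mean = 1.0,
                       baseline_log10cpm_sd = 1.5,
                       marker_baseline_log10cpm_range = c(0.8, 1.5),
                       dispersion = 0.1,
                       lib_size = 2e6,
                       n_atlas_conditions = 40,
                       atlas_replicates = 3,
                       n_mags = 20,
                       n_mag_samples = 40,
                       genes_per_mag = 1200,
                       planted_sexual_frac = 0.1,
                       mag_depth_meanlog = log(1.2e5),
                       mag_depth_sdlog = 0.25,
                       low_depth_frac = 0.05,
                       marker_veg_meanlog = log(200),
                       marker_veg_sdlog = 1,
                       marker_sex_meanlog = log(2e4),
                       marker_sex_sdlog = 0.5,
                       n_reference_samples = 140,
                       reference_genes_per_family = 8,
                       tree_n_refs = 6,
                       tree_n_outgroups = 3,
                       tree_n_inside = 4,
                       tree_n_outside = 3,
                       tree_support = 100,
                       hit_n_true = 25,
                       hit_n_decoy = 25,
                       hit_true_score = 85,
                       hit_decoy_score = 40,
                       hit_score_sd = 8,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$planted_sexual_frac < 0 || cfg$planted_sexual_frac > 1 ||
      cfg$low_depth_frac < 0 || cfg$low_depth_frac > 1)
    stop("fractions must lie in [0, 1]")
  if (cfg$n_families < cfg$n_planted_markers + cfg$n_planted_controls)
    stop("n_families too small for the planted families")
  if (is.null(cfg$rng_seed)) stop("a seed is mandatory for reproducibility")
  structure(cfg, class = "sim_config")
}

#' Simulate the multi-species sexual-reproduction RNA-seq experiment
#'
#' Generates, for each species, an `expr_matrix` with `replicates` sexual
#' samples per stage and `replicates` vegetative controls, plus a
#' `gene_family_table` and the ground truth. Background families occur in
#' each species with probability `present_prob` (planted families in all);
#' planted marker families are diatom-specific, single copy, and
#' upregulated by their drawn log2 fold change in the sexual samples of the
#' affected stages of every species; planted control families are flat.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list: `expr` (named list of `expr_matrix` per species),
#'   `families` (a `gene_family_table`), `truth` (planted ids, effects,
#'   per-gene baseline and sexual-mean CPM for the first species).
#' @export
simulate_multispecies <- function(config = sim_config(),
                                  seed = config$rng_seed) {
  set.seed(seed)
  nf <- config$n_families
  fam_ids <- sprintf("FAM%04d", seq_len(nf))
  n_mark <- config$n_planted_markers
  n_ctl <- config$n_planted_controls
  planted_markers <- if (n_mark) fam_ids[seq_len(n_mark)] else character()
  planted_controls <- if (n_ctl)
    fam_ids[n_mark + seq_len(n_ctl)] else character()
  species <- paste0("species", seq_len(config$n_species))
  clades <- ifelse(seq_len(config$n_species) == config$n_species,
                   "centric", "raphid_pennate")
  names(clades) <- species

  diatom_specific <- stats::runif(nf) < config$diatom_specific_prob
  names(diatom_specific) <- fam_ids
  diatom_specific[planted_markers] <- TRUE
  # baseline expression per family (shared across species)
  base_l10 <- stats::rnorm(nf, config$baseline_log10cpm_mean,
                           config$baseline_log10cpm_sd)
  names(base_l10) <- fam_ids
  if (n_mark)
    base_l10[planted_markers] <- stats::runif(
      n_mark, config$marker_baseline_log10cpm_range[1],
      config$marker_baseline_log10cpm_range[2])
  effects <- if (n_mark)
    stats::setNames(stats::runif(n_mark, config$effect_range[1],
                                 config$effect_range[2]), planted_markers)
  else stats::setNames(numeric(0), character(0))

  # family presence and copy number per species
  genes <- list(); fam_rows <- list()
  for (sp in species) {
    present <- stats::runif(nf) < config$present_prob
    present[fam_ids %in% c(planted_markers, planted_controls)] <- TRUE
    copies <- ifelse(stats::runif(nf) < config$dup_prob, 2L, 1L)
    copies[fam_ids %in% c(planted_markers, planted_controls)] <- 1L
    copies[!present] <- 0L
    idx <- rep(which(present), copies[present])
    cp <- unlist(lapply(which(present), function(i) seq_len(copies[i])))
    genes[[sp]] <- data.frame(
      gene_id = sprintf("%s_%s_c%d", sp, fam_ids[idx], cp),
      family_id = fam_ids[idx], species = sp, stringsAsFactors = FALSE)
    fam_rows[[sp]] <- data.frame(
      family_id = fam_ids[present], species = sp,
      copy_count = copies[present],
      diatom_specific = diatom_specific[present],
      stringsAsFactors = FALSE)
  }
  family_table <- gene_family_table(do.call(rbind, genes),
                                    do.call(rbind, fam_rows))

  stages <- config$stages
  reps <- config$replicates
  expr <- list()
  for (sp in species) {
    g <- genes[[sp]]
    ng <- nrow(g)
    # per-gene baseline with a small copy-level jitter
    gene_base <- 10^(base_l10[g$family_id] + stats::rnorm(ng, 0, 0.25))
    lens <- sample(500:3000, ng, replace = TRUE)
    cond <- data.frame(
      condition_class = c(rep("sexual", length(stages) * reps),
                          rep("vegetative_control", reps)),
      stage = c(rep(stages, each = reps), rep("none", reps)),
      replicate = c(rep(seq_len(reps), length(stages)), seq_len(reps)),
      stringsAsFactors = FALSE)
    cond$condition_label <- ifelse(cond$condition_class == "sexual",
                                   paste0("sex_", cond$stage), "vegetative")
    cond$sample_id <- sprintf("%s_%s_r%d", sp,
                              ifelse(cond$stage == "none", "veg", cond$stage),
                              cond$replicate)
    cond$species <- sp
    mu <- matrix(gene_base, ng, nrow(cond))
    if (n_mark) {
      mk <- g$family_id %in% planted_markers
      aff <- cond$condition_class == "sexual" &
        cond$stage %in% config$stages_affected
      mu[mk, aff] <- mu[mk, aff, drop = FALSE] *
        2^effects[g$family_id[mk]]
    }
    lib <- config$lib_size * exp(stats::rnorm(nrow(cond), 0, 0.15))
    mu_counts <- sweep(mu, 2, lib / 1e6, "*")
    counts <- matrix(stats::rnbinom(length(mu_counts), mu = mu_counts,
                                    size = 1 / config$dispersion), ng)
    dimnames(counts) <- list(g$gene_id, cond$sample_id)
    expr[[sp]] <- expression_matrix(
      counts, cond[c("sample_id", "species", "condition_class", "stage",
                     "condition_label", "replicate")],
      stats::setNames(lens, g$gene_id))
  }
  sexual_mean_cpm <- lapply(expr, function(x) {
    g <- rownames(x$counts)
    fam <- family_of(family_table, g)
    base <- 10^(base_l10[fam])
    up <- fam %in% planted_markers
    base[up] <- base[up] * 2^effects[fam[up]]
    stats::setNames(base, g)
  })
  list(expr = expr, families = family_table,
       truth = list(planted_markers = planted_markers,
                    planted_controls = planted_controls,
                    effects = effects, species_clade = clades,
                    baseline_log10cpm = base_l10,
                    sexual_mean_cpm = sexual_mean_cpm))
}

#' Simulate a vegetative expression atlas
#'
#' Atlas conditions for the first species of a [simulate_multispecies()]
#' run: `n_atlas_conditions` condition groups of `atlas_replicates` samples
#' each, with a per-condition log-normal shift around the vegetative
#' baseline. Planted (clean) marker families are held at a noise-floor
#' expression; families listed in `leaky` instead express the given
#' fraction of their sexual mean, stressing the specificity filter.
#'
#' @param sim result of [simulate_multispecies()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param leaky named numeric vector family_id -> fraction of the sexual
#'   mean expressed in the atlas.
#' @return an `expr_matrix` of atlas samples for the first species.
#' @export
simulate_atlas <- function(sim, config = sim_config(),
                           seed = config$rng_seed, leaky = NULL) {
  set.seed(seed + 1000L)
  sp <- names(sim$expr)[1]
  x <- sim$expr[[sp]]
  g <- rownames(x$counts)
  fam <- family_of(sim$families, g)
  base <- 10^(sim$truth$baseline_log10cpm[fam] + stats::rnorm(length(g), 0, 0.25))
  mk <- fam %in% sim$truth$planted_markers
  base[mk] <- 0.02  # noise floor for clean sex-specific markers
  if (!is.null(leaky)) {
    lk <- fam %in% names(leaky)
    base[lk] <- sim$truth$sexual_mean_cpm[[sp]][g[lk]] * leaky[fam[lk]]
  }
  nc <- config$n_atlas_conditions
  reps <- config$atlas_replicates
  cond_shift <- stats::rnorm(nc, 0, 0.3)  # log10 condition effect
  cond <- data.frame(
    condition_class = "atlas", stage = "none",
    condition_label = rep(sprintf("cond%02d", seq_len(nc)), each = reps),
    replicate = rep(seq_len(reps), nc), stringsAsFactors = FALSE)
  cond$sample_id <- sprintf("%s_atlas_%s_r%d", sp, cond$condition_label,
                            cond$replicate)
  cond$species <- sp
  mu <- outer(base, 10^rep(cond_shift, each = reps))
  lib <- config$lib_size * exp(stats::rnorm(nrow(cond), 0, 0.15))
  mu_counts <- sweep(mu, 2, lib / 1e6, "*")
  counts <- matrix(stats::rnbinom(length(mu_counts), mu = mu_counts,
                                  size = 1 / config$dispersion), length(g))
  dimnames(counts) <- list(g, cond$sample_id)
  expression_matrix(counts,
                    cond[c("sample_id", "species", "condition_class", "stage",
                           "condition_label", "replicate")],
                    x$gene_lengths)
}

# marker/control label sets of the simulated survey
mag_marker_labels <- function() {
  list(
    markers = marker_panel(
      labels = c("SPO11-2", "M1", "M2", "M3", "M4",
                 "SIG1", "DNAH9/11/17", "DNAH5/8", "DRC4"),
      family_ids = c("FAM_SPO11", "FAM_M1", "FAM_M2", "FAM_M3", "FAM_M4",
                     "FAM_SIG1", "FAM_DNAH9", "FAM_DNAH5", "FAM_DRC4"),
      applicability = c("all_diatoms", "raphid_pennate", "raphid_pennate",
                        "all_diatoms", "raphid_pennate",
                        "centric", "centric", "centric", "centric"),
      positive_control = "SPO11-2"),
    controls = marker_panel(
      labels = c("PC", "C1", "C2", "C3", "C4"),
      family_ids = c("FAM_PC", "FAM_C1", "FAM_C2", "FAM_C3", "FAM_C4"),
      applicability = rep("all_diatoms", 5),
      positive_control = "PC"))
}

#' Simulate a MAG-resolved metatranscriptome survey
#'
#' Emulates the structure of a MAG x station x depth survey together with
#' the laboratory calibration reference. Each MAG carries
#' `genes_per_mag` background genes plus one homolog of every marker
#' applicable to its clade, of the positive control, and of each control
#' family. Vegetative (non-sexual) marker/control expression is drawn from
#' the same log-normal TPM distribution used for the calibration reference,
#' so the percentile threshold has a designed ~5% per-draw exceedance;
#' planted sexual cells draw their panel markers and the positive control
#' from a high distribution instead. Read counts are multinomial given the
#' TPM profile and a log-normal sequencing depth; a `low_depth_frac`
#' fraction of cells is given a shallow depth so the retention filter has
#' work to do.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param planted_frac override of `config$planted_sexual_frac` (set 0 for
#'   a no-signal dataset, e.g. for the control audit).
#' @return list: `dataset` (a `mag_dataset`), `assignment` and
#'   `control_assignment` (mag_id, gene_id, marker_label), `panel` and
#'   `control_panel` (`marker_panel`s), `reference` (calibration
#'   `expr_matrix`), `families` (`gene_family_table` for the reference),
#'   `truth` (data.frame mag_id, sample_id, sexual).
#' @export
simulate_mag_dataset <- function(config = sim_config(),
                                 seed = config$rng_seed,
                                 planted_frac = config$planted_sexual_frac) {
  set.seed(seed + 2000L)
  panels <- mag_marker_labels()
  panel <- panels$markers
  control_panel <- panels$controls
  all_labels <- c(panel$label, control_panel$label)
  all_fams <- c(panel$family_id, control_panel$family_id)

  # ---- calibration reference: one vegetative laboratory experiment ----
  npf <- config$reference_genes_per_family
  ref_marker_genes <- unlist(lapply(all_fams, function(f)
    sprintf("ref_%s_g%d", f, seq_len(npf))))
  ref_marker_fam <- rep(all_fams, each = npf)
  nbg_ref <- config$genes_per_mag
  ref_bg_genes <- sprintf("ref_bg%04d", seq_len(nbg_ref))
  ref_genes <- c(ref_marker_genes, ref_bg_genes)
  ref_lens <- stats::setNames(sample(500:2500, length(ref_genes),
                                     replace = TRUE), ref_genes)
  nrs <- config$n_reference_samples
  nmk <- length(ref_marker_genes)
  w_mark <- matrix(stats::rlnorm(nmk * nrs, config$marker_veg_meanlog,
                                 config$marker_veg_sdlog), nmk)
  w_bg <- matrix(stats::rlnorm(nbg_ref * nrs, log(1000), 1), nbg_ref)
  w <- rbind(w_mark, w_bg)
  depth <- round(stats::rlnorm(nrs, config$mag_depth_meanlog,
                               config$mag_depth_sdlog))
  counts <- vapply(seq_len(nrs), function(s) {
    pr <- w[, s] * ref_lens
    stats::rmultinom(1, depth[s], pr / sum(pr))[, 1]
  }, numeric(length(ref_genes)))
  dimnames(counts) <- list(ref_genes,
                           sprintf("refveg_s%03d", seq_len(nrs)))
  ref_meta <- data.frame(
    sample_id = colnames(counts), species = "reference_pennate",
    condition_class = "vegetative_control", stage = "none",
    condition_label = "vegetative",
    replicate = seq_len(nrs), stringsAsFactors = FALSE)
  reference <- expression_matrix(counts, ref_meta, ref_lens)
  fam_genes <- data.frame(gene_id = ref_marker_genes,
                          family_id = ref_marker_fam,
                          species = "reference_pennate",
                          stringsAsFactors = FALSE)
  fam_attr <- data.frame(family_id = all_fams, species = "reference_pennate",
                         copy_count = npf, diatom_specific = TRUE,
                         stringsAsFactors = FALSE)
  families <- gene_family_table(fam_genes, fam_attr)

  # ---- the survey ----
  n_mags <- config$n_mags
  n_samp <- config$n_mag_samples
  mags <- data.frame(
    mag_id = sprintf("mag%02d", seq_len(n_mags)),
    clade = rep(c("raphid_pennate", "centric"), length.out = n_mags),
    genus = sprintf("Genus%02d", rep(seq_len(max(1, n_mags %/% 2)),
                                     length.out = n_mags)),
    stringsAsFactors = FALSE)
  n_stations <- ceiling(n_samp / 2)
  samples <- data.frame(
    sample_id = sprintf("tara_s%03d", seq_len(n_samp)),
    station = sprintf("st%02d", rep(seq_len(n_stations), each = 2,
                                    length.out = n_samp)),
    depth = rep(c("SRF", "DCM"), length.out = n_samp),
    size_fraction = "20-180", season = "spring", stringsAsFactors = FALSE)

  assignment <- do.call(rbind, lapply(seq_len(n_mags), function(i) {
    labs <- c(panel_for_clade(panel, mags$clade[i]), "SPO11-2")
    data.frame(mag_id = mags$mag_id[i],
               gene_id = sprintf("%s_%s", mags$mag_id[i], gsub("/", "", labs)),
               marker_label = labs, stringsAsFactors = FALSE)
  }))
  control_assignment <- do.call(rbind, lapply(seq_len(n_mags), function(i) {
    labs <- control_panel$label
    data.frame(mag_id = mags$mag_id[i],
               gene_id = sprintf("%s_%s", mags$mag_id[i], labs),
               marker_label = labs, stringsAsFactors = FALSE)
  }))

  nbg <- config$genes_per_mag
  truth <- expand.grid(mag_id = mags$mag_id, sample_id = samples$sample_id,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$sexual <- stats::runif(nrow(truth)) < planted_frac
  truth$shallow <- stats::runif(nrow(truth)) < config$low_depth_frac &
    !truth$sexual

  expr_parts <- vector("list", n_mags)
  for (i in seq_len(n_mags)) {
    mg <- mags$mag_id[i]
    asg <- assignment[assignment$mag_id == mg, , drop = FALSE]
    casg <- control_assignment[control_assignment$mag_id == mg, , drop = FALSE]
    mk_genes <- c(asg$gene_id, casg$gene_id)
    mk_labels <- c(asg$marker_label, casg$marker_label)
    bg_genes <- sprintf("%s_bg%04d", mg, seq_len(nbg))
    genes <- c(mk_genes, bg_genes)
    lens <- sample(500:2500, length(genes), replace = TRUE)
    tr <- truth[truth$mag_id == mg, , drop = FALSE]
    tr <- tr[match(samples$sample_id, tr$sample_id), , drop = FALSE]
    nmkg <- length(mk_genes)
    w_mk <- matrix(stats::rlnorm(nmkg * n_samp, config$marker_veg_meanlog,
                                 config$marker_veg_sdlog), nmkg)
    sex_cols <- which(tr$sexual)
    if (length(sex_cols)) {
      # panel markers and SPO11-2 high; control genes stay vegetative
      hot <- mk_labels %in% panel$label
      w_mk[hot, sex_cols] <- matrix(
        stats::rlnorm(sum(hot) * length(sex_cols),
                      config$marker_sex_meanlog, config$marker_sex_sdlog),
        sum(hot))
    }
    w_bg <- matrix(stats::rlnorm(nbg * n_samp, log(1000), 1), nbg)
    w <- rbind(w_mk, w_bg)
    depth <- round(stats::rlnorm(n_samp, config$mag_depth_meanlog,
                                 config$mag_depth_sdlog))
    depth[tr$shallow] <- round(stats::runif(sum(tr$shallow), 2000, 6000))
    cnt <- vapply(seq_len(n_samp), function(s) {
      pr <- w[, s] * lens
      stats::rmultinom(1, depth[s], pr / sum(pr))[, 1]
    }, numeric(length(genes)))
    nz <- which(cnt > 0)
    expr_parts[[i]] <- data.frame(
      mag_id = mg,
      sample_id = samples$sample_id[((nz - 1) %/% length(genes)) + 1],
      gene_id = genes[((nz - 1) %% length(genes)) + 1],
      count = cnt[nz],
      length = lens[((nz - 1) %% length(genes)) + 1],
      stringsAsFactors = FALSE)
  }
  dataset <- mag_dataset(do.call(rbind, expr_parts), mags, samples)
  list(dataset = dataset, assignment = assignment,
       control_assignment = control_assignment,
       panel = panel, control_panel = control_panel,
       reference = reference, families = families,
       truth = truth[c("mag_id", "sample_id", "sexual")])
}

#' Simulate an annotated marker tree
#'
#' Random subtree of reference tips (with `tree_n_inside` query tips
#' attached inside it) joined to a subtree of outgroup tips (with
#' `tree_n_outside` query tips among them) by long stem branches, so the
#' reference clade is recovered intact after midpoint rooting. Internal
#' nodes carry the configured support value.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list: `tree` (an `annotated_tree`), `truth` (character vector of
#'   the query tips planted inside the reference clade).
#' @export
simulate_marker_tree <- function(config = sim_config(),
                                 seed = config$rng_seed) {
  set.seed(seed + 3000L)
  rand_subtree <- function(labels) {
    n <- length(labels)
    if (n == 1) return(sprintf("%s:%.4f", labels, stats::runif(1, 0.05, 0.3)))
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.3))
    tr$tip.label <- sample(labels)
    sub(";$", "", ape::write.tree(tr))
  }
  refs <- sprintf("ref%d", seq_len(config$tree_n_refs))
  qin <- if (config$tree_n_inside)
    sprintf("qin%d", seq_len(config$tree_n_inside)) else character()
  outs <- sprintf("out%d", seq_len(config$tree_n_outgroups))
  qout <- if (config$tree_n_outside)
    sprintf("qout%d", seq_len(config$tree_n_outside)) else character()
  nwk <- sprintf("(%s:10,%s:10);",
                 rand_subtree(c(refs, qin)), rand_subtree(c(outs, qout)))
  tree <- ape::read.tree(text = nwk)
  tree$node.label <- rep(as.character(config$tree_support), tree$Nnode)
  roles <- c(stats::setNames(rep("reference", length(refs)), refs),
             stats::setNames(rep("query", length(qin)), qin),
             stats::setNames(rep("outgroup", length(outs)), outs),
             stats::setNames(rep("query", length(qout)), qout))
  list(tree = annotated_tree(tree, roles), truth = qin)
}

#' Simulate a HMMER hit table
#'
#' True marker homologs draw bit scores from a high normal distribution and
#' decoys from a low one straddling the 50-bit cutoff; E-values are a
#' deterministic monotone transform of the score. True hits sit on diatom
#' MAGs; decoys are split between diatom and non-diatom taxa.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list: `hits` (data.frame as from [parse_tblout()]), `truth`
#'   (logical vector: is the hit a true homolog).
#' @export
simulate_hit_table <- function(config = sim_config(),
                               seed = config$rng_seed) {
  set.seed(seed + 4000L)
  n_t <- config$hit_n_true; n_d <- config$hit_n_decoy
  score <- c(stats::rnorm(n_t, config$hit_true_score, config$hit_score_sd),
             stats::rnorm(n_d, config$hit_decoy_score, config$hit_score_sd))
  is_true <- rep(c(TRUE, FALSE), c(n_t, n_d))
  taxa <- ifelse(is_true, "diatom_mag",
                 sample(c("diatom_mag", "haptophyte_mag"), n_t + n_d,
                        replace = TRUE))
  hits <- data.frame(
    target_id = sprintf("env%03d", seq_len(n_t + n_d)),
    marker_label = sample(c("M1", "M2", "M3", "M4"), n_t + n_d,
                          replace = TRUE),
    evalue = 10^(-score / 4),
    score = round(score, 1),
    source_taxon = taxa, stringsAsFactors = FALSE)
  list(hits = hits, truth = is_true)
}
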