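# Synthetic two-platform expression studies with known class structure and
# known perturbed pathways, at the scale of a custom leukemia array:
# ~2228 probes for ~2016 genes in 334 pathways, 4 replicate spots per
# probe, small cohorts per class.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: a custom array
#' of 2228 probes over 2016 genes (so ~10.5% of genes carry two probes)
#' organized in 334 pathways, four replicate spots per probe, and a
#' pediatric-scale cohort of 3 normal, 7 ALL and 7 AML samples.
#'
#' @param seed Integer master seed; all stage streams derive from it
#'   deterministically (must be below 2e7 so derived seeds stay within
#'   integer range).
#' @param n_genes,n_pathways Gene universe and pathway count.
#' @param pathway_size_range Inclusive range of pathway sizes.
#' @param two_probe_fraction Fraction of genes measured by two probes
#'   (default 212/2016, giving 2228 probes at the default gene count).
#' @param n_replicates Replicate spots per probe (default 4).
#' @param class_sizes Named integer vector, class -> sample count.
#' @param perturbations Data.frame with columns `pathway`, `class`, `delta`:
#'   class-specific pathway effects in log10 units. Under a positive delta
#'   the pathway's activator genes rise and its repressor genes fall by
#'   `10^(delta * sign(ARR))`, driving PAS2 toward +delta.
#' @param noise_sd Replicate noise SD on the log10 scale (default 0.3,
#'   a realistic microarray spot-level spread).
#' @param probe_affinity_sd Per-probe affinity SD on the log10 scale; the
#'   affinity multiplies all samples equally and cancels in CNR.
#' @param baseline_log_mean,baseline_log_sd Gene baseline distribution
#'   (log10 scale): baselines are `10^Normal(mean, sd)`.
#' @param arr_probs Sampling weights for ARR values (-1, -0.5, 0, 0.5, 1);
#'   default puts most mass on the +-1 activator/repressor roles.
#' @param platform List `(gain, power)`: a monotone power-law platform
#'   distortion `gain * value^power` (rank-preserving, hence
#'   AUC-invariant).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2016L,
                       n_pathways = 334L,
                       pathway_size_range = c(4L, 20L),
                       two_probe_fraction = 212 / 2016,
                       n_replicates = 4L,
                       class_sizes = c(Normal = 3L, ALL = 7L, AML = 7L),
                       perturbations = NULL,
                       noise_sd = 0.3,
                       probe_affinity_sd = 0.2,
                       baseline_log_mean = 2.5,
                       baseline_log_sd = 0.6,
                       arr_probs = c(0.35, 0.075, 0.10, 0.075, 0.40),
                       platform = list(gain = 1, power = 1)) {
  stopifnot(seed == floor(seed), abs(seed) < 2e7,
            n_genes >= 1L, n_pathways >= 1L, n_replicates >= 1L,
            length(pathway_size_range) == 2L,
            pathway_size_range[1] >= 1L,
            pathway_size_range[2] >= pathway_size_range[1],
            two_probe_fraction >= 0, two_probe_fraction <= 1,
            noise_sd >= 0, probe_affinity_sd >= 0,
            length(arr_probs) == 5L, all(arr_probs >= 0), sum(arr_probs) > 0,
            is.numeric(platform$gain), platform$gain > 0,
            is.numeric(platform$power), platform$power > 0)
  if (is.null(names(class_sizes)) || any(!nzchar(names(class_sizes))))
    stop("class_sizes must be named by class label")
  stopifnot(all(class_sizes >= 1L))
  if (pathway_size_range[2] > n_genes)
    stop("pathway_size_range exceeds the gene universe")
  if (is.null(perturbations))
    perturbations <- data.frame(pathway = character(0), class = character(0),
                                delta = numeric(0), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(perturbations),
            all(c("pathway", "class", "delta") %in% names(perturbations)),
            all(is.finite(perturbations$delta)))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 two_probe_fraction = two_probe_fraction,
                 n_replicates = as.integer(n_replicates),
                 class_sizes = class_sizes, perturbations = perturbations,
                 noise_sd = noise_sd, probe_affinity_sd = probe_affinity_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 arr_probs = arr_probs, platform = platform),
            class = "sim_config")
}

# Deterministic per-stage sub-stream seeding from the master seed.
stage_seed <- function(cfg, stage) {
  set.seed(cfg$seed * 100L + as.integer(stage))
}

sim_gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

#' Simulate a pathway database
#'
#' Pathway sizes are uniform on `pathway_size_range`; member genes are
#' drawn without replacement within a pathway (overlap across pathways is
#' allowed) and ARR weights are drawn with `arr_probs`.
#'
#' @param cfg A [sim_config()].
#' @return A [pathway_db()] with pathways named `"Pathway 001"`, ...
#' @export
simulate_pathway_db <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  stage_seed(cfg, 1L)
  genes <- sim_gene_ids(cfg)
  size_choices <- seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), cfg$n_pathways,
                                   replace = TRUE)]
  pws <- lapply(seq_len(cfg$n_pathways), function(i) {
    g <- sample(genes, sizes[i])
    arr <- sample(arr_values(), sizes[i], replace = TRUE,
                  prob = cfg$arr_probs)
    names(arr) <- g
    pathway(sprintf("Pathway %03d", i), arr,
            description = sprintf("simulated pathway %d", i))
  })
  pathway_db(pws)
}

# Core cohort generator; baselines/probe layout may be supplied so that two
# platforms can share them. stream_offset separates noise streams.
simulate_cohort_impl <- function(cfg, db, baselines, probe_gene, affinity,
                                 cohort, stream_offset) {
  genes <- sim_gene_ids(cfg)
  probes <- names(probe_gene)
  classes <- rep(names(cfg$class_sizes), cfg$class_sizes)
  sample_ids <- unlist(lapply(names(cfg$class_sizes), function(cl)
    sprintf("%s_%s_%d", cohort, cl, seq_len(cfg$class_sizes[[cl]]))),
    use.names = FALSE)
  names(classes) <- sample_ids

  # class x gene log10 effects from the perturbation truth table
  eff <- matrix(0, nrow = cfg$n_genes, ncol = length(cfg$class_sizes),
                dimnames = list(genes, names(cfg$class_sizes)))
  pert <- cfg$perturbations
  for (i in seq_len(nrow(pert))) {
    p <- pert$pathway[i]
    if (!p %in% names(db)) stop("perturbed pathway not in database: ", p)
    if (!pert$class[i] %in% names(cfg$class_sizes))
      stop("perturbed class not in class_sizes: ", pert$class[i])
    arr <- db[[p]]$arr
    eff[names(arr), pert$class[i]] <-
      eff[names(arr), pert$class[i]] + pert$delta[i] * sign(arr)
  }

  stage_seed(cfg, 4L + stream_offset)
  n_p <- length(probes); n_r <- cfg$n_replicates; n_s <- length(sample_ids)
  noise <- if (cfg$noise_sd > 0)
    array(stats::rnorm(n_p * n_r * n_s, 0, cfg$noise_sd), dim = c(n_p, n_r, n_s))
  else array(0, dim = c(n_p, n_r, n_s))
  mu <- baselines[probe_gene] * affinity            # per probe
  ints <- array(0, dim = c(n_p, n_r, n_s),
                dimnames = list(probes, NULL, sample_ids))
  for (s in seq_len(n_s)) {
    mus <- mu * 10^eff[probe_gene, classes[s]]
    ints[, , s] <- mus * 10^noise[, , s]
  }
  ints <- cfg$platform$gain * ints^cfg$platform$power
  ints[ints < 0] <- 0
  pm <- probe_matrix(ints, probe_gene, classes)
  structure(list(
    pathway_db = db,
    probe_matrix = pm,
    annotation = data.frame(sample_id = sample_ids,
                            class = unname(classes),
                            cohort = cohort, stringsAsFactors = FALSE),
    truth = pert),
    class = "sim_study")
}

# Shared per-study draws: gene baselines, probe layout, probe affinities.
sim_baselines <- function(cfg) {
  stage_seed(cfg, 2L)
  b <- 10^stats::rnorm(cfg$n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(b) <- sim_gene_ids(cfg)
  b
}

sim_probe_layout <- function(cfg) {
  stage_seed(cfg, 3L)
  genes <- sim_gene_ids(cfg)
  n_two <- round(cfg$two_probe_fraction * cfg$n_genes)
  two <- sample(genes, n_two)
  probe_gene <- c(genes, two)[order(c(genes, two))]
  names(probe_gene) <- sprintf("P%04d", seq_along(probe_gene))
  affinity <- 10^stats::rnorm(length(probe_gene), 0, cfg$probe_affinity_sd)
  names(affinity) <- names(probe_gene)
  list(probe_gene = probe_gene, affinity = affinity)
}

#' Simulate one cohort study
#'
#' Gene baselines are log-normal; for a sample of class *c* the expected
#' value of gene *g* is `baseline(g) * 10^(sum of delta * sign(ARR))` over
#' the class's perturbed pathways containing *g*, so activators rise and
#' repressors fall under a positive delta. Each probe has a log-normal
#' affinity multiplier (shared by all samples), each replicate spot
#' multiplicative log-normal noise, and the platform applies a monotone
#' power-law gain. The same seed reproduces the study exactly.
#'
#' @param cfg A [sim_config()].
#' @param db Optional [pathway_db()]; simulated from `cfg` when omitted.
#' @param cohort Cohort label used in sample ids.
#' @return A `sim_study`: list with `pathway_db`, `probe_matrix`,
#'   `annotation` (sample_id, class, cohort) and `truth` (the perturbation
#'   table).
#' @export
simulate_cohort <- function(cfg, db = NULL, cohort = "cohort1") {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(db)) db <- simulate_pathway_db(cfg)
  lay <- sim_probe_layout(cfg)
  simulate_cohort_impl(cfg, db, sim_baselines(cfg), lay$probe_gene,
                       lay$affinity, cohort, stream_offset = 0L)
}

#' Simulate a two-platform study pair
#'
#' Two cohorts share the pathway database and the gene baselines but are
#' measured on platforms with distinct monotone distortions, have separate
#' sample cohorts (by default a pediatric-scale 3/7 cohort and an
#' adult-scale 17/30 cohort) and may carry shared, opposite or private
#' pathway perturbations — so cross-cohort concordance can be tested
#' against known overlap.
#'
#' @param cfg A [sim_config()] describing cohort A (its `platform` and
#'   `perturbations` apply to A).
#' @param perturbations_b Perturbation table for cohort B.
#' @param class_sizes_b Class sizes for cohort B (default
#'   `c(Normal = 17, AML = 30)`).
#' @param platform_b Platform distortion for cohort B (default
#'   `list(gain = 0.75, power = 1.15)`).
#' @return List with `a` and `b`, each a `sim_study`.
#' @export
simulate_two_platform_study <- function(cfg,
                                        perturbations_b = NULL,
                                        class_sizes_b = c(Normal = 17L, AML = 30L),
                                        platform_b = list(gain = 0.75,
                                                          power = 1.15)) {
  stopifnot(inherits(cfg, "sim_config"))
  db <- simulate_pathway_db(cfg)
  base <- sim_baselines(cfg)
  lay <- sim_probe_layout(cfg)
  cfg_b <- sim_config(seed = cfg$seed, n_genes = cfg$n_genes,
                      n_pathways = cfg$n_pathways,
                      pathway_size_range = cfg$pathway_size_range,
                      two_probe_fraction = cfg$two_probe_fraction,
                      n_replicates = cfg$n_replicates,
                      class_sizes = class_sizes_b,
                      perturbations = perturbations_b,
                      noise_sd = cfg$noise_sd,
                      probe_affinity_sd = cfg$probe_affinity_sd,
                      baseline_log_mean = cfg$baseline_log_mean,
                      baseline_log_sd = cfg$baseline_log_sd,
                      arr_probs = cfg$arr_probs,
                      platform = platform_b)
  list(a = simulate_cohort_impl(cfg, db, base, lay$probe_gene, lay$affinity,
                                "cohortA", stream_offset = 0L),
       b = simulate_cohort_impl(cfg_b, db, base, lay$probe_gene, lay$affinity,
                                "cohortB", stream_offset = 10L))
}

#' Write a simulated study to pipeline input files
#'
#' Emits the same formats the pipeline reads: a probe-level TSV, a sample
#' annotation TSV, an extended GMT pathway database and a truth TSV
#' (pathway, class, delta).
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_sim_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(probes = file.path(dir, "probes.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             pathways = file.path(dir, "pathways.gmtx"),
             truth = file.path(dir, "truth.tsv"))
  write_probe_tsv(study$probe_matrix, paths["probes"])
  utils::write.table(study$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  write_pathway_db(study$pathway_db, paths["pathways"])
  utils::write.table(study$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
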