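test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, n_genes = 80, n_pathways = 12,
                    class_sizes = c(Normal = 3, AML = 4))
  s1 <- simulate_cohort(cfg); s2 <- simulate_cohort(cfg)
  expect_identical(s1$probe_matrix$intensities, s2$probe_matrix$intensities)
  expect_identical(write_pathway_db(s1$pathway_db, tempfile()) |> readLines(),
                   write_pathway_db(s2$pathway_db, tempfile()) |> readLines())
  s3 <- simulate_cohort(sim_config(seed = 10, n_genes = 80, n_pathways = 12,
                                   class_sizes = c(Normal = 3, AML = 4)))
  expect_false(identical(s1$probe_matrix$intensities,
                         s3$probe_matrix$intensities))
})

test_that("the simulated database matches the configured array scale", {
  cfg <- sim_config(seed = 2)
  db <- simulate_pathway_db(cfg)
  expect_length(db, 334)
  expect_lte(length(gene_universe(db)), 2016)
  sizes <- vapply(db, function(p) length(p$arr), integer(1))
  expect_true(all(sizes >= 4 & sizes <= 20))
  expect_true(all(unlist(lapply(db, function(p) p$arr)) %in% arr_values()))
  # fixed size range is honored exactly
  db5 <- simulate_pathway_db(sim_config(seed = 2, n_genes = 50,
                                        n_pathways = 8,
                                        pathway_size_range = c(5, 5)))
  expect_true(all(vapply(db5, function(p) length(p$arr), integer(1)) == 5))
  # probe count emulates the array: ~2228 probes for 2016 genes
  st <- simulate_cohort(sim_config(seed = 2, class_sizes = c(Normal = 2)))
  expect_equal(dim(st$probe_matrix$intensities)[1], 2228)
  expect_equal(dim(st$probe_matrix$intensities)[2], 4)
})

test_that("a strong perturbation yields perfect separation with the right sign", {
  pert <- data.frame(pathway = "Pathway 003", class = "AML", delta = 2)
  cfg <- sim_config(seed = 21, n_genes = 400, n_pathways = 30,
                    class_sizes = c(Normal = 3, AML = 7),
                    perturbations = pert, noise_sd = 0.01)
  st <- simulate_cohort(cfg)
  m <- run_pathway_markers(st)
  rec <- m[m$feature_id == "Pathway 003", ]
  expect_equal(rec$auc, 1)
  expect_equal(rec$direction, "up")
  expect_gt(rec$mean_case, 0)
  # negative delta drives the score negative
  cfg_dn <- sim_config(seed = 21, n_genes = 400, n_pathways = 30,
                       class_sizes = c(Normal = 3, AML = 7),
                       perturbations = transform(pert, delta = -2),
                       noise_sd = 0.01)
  m_dn <- run_pathway_markers(simulate_cohort(cfg_dn))
  rec_dn <- m_dn[m_dn$feature_id == "Pathway 003", ]
  expect_equal(rec_dn$auc, 1)
  expect_equal(rec_dn$direction, "down")
  expect_lt(rec_dn$mean_case, 0)
})

test_that("with no perturbation no pathway separates systematically", {
  aucs <- numeric(0)
  for (s in 101:104) {
    cfg <- sim_config(seed = s, n_genes = 300, n_pathways = 40,
                      class_sizes = c(Normal = 3, AML = 7))
    m <- run_pathway_markers(simulate_cohort(cfg))
    aucs <- c(aucs, mean(m$auc))
  }
  expect_true(all(aucs > 0.5 & aucs < 0.8))
})

test_that("noise-free recovery matches the closed-form effect size", {
  delta <- 0.7
  pert <- data.frame(pathway = "Pathway 002", class = "AML", delta = delta)
  cfg <- sim_config(seed = 13, n_genes = 150, n_pathways = 10,
                    class_sizes = c(Normal = 3, AML = 3),
                    perturbations = pert, noise_sd = 0,
                    two_probe_fraction = 0,
                    arr_probs = c(0.5, 0, 0, 0, 0.5))  # |ARR| = 1 only
  st <- simulate_cohort(cfg)
  expr <- aggregate_probes(st$probe_matrix, round = FALSE)
  ctrl <- st$annotation$sample_id[st$annotation$class == "Normal"]
  cnr <- compute_cnr(expr, ctrl, pseudocount = 0)
  pas <- compute_pas(cnr, st$pathway_db)
  aml <- st$annotation$sample_id[st$annotation$class == "AML"]
  expect_equal(unname(pas$pas2["Pathway 002", aml]),
               rep(delta, length(aml)), tolerance = 1e-6)
  # pathways sharing no genes with the perturbed one score exactly zero
  pg <- names(st$pathway_db[["Pathway 002"]]$arr)
  untouched <- Filter(function(p) p != "Pathway 002" &&
                        !any(names(st$pathway_db[[p]]$arr) %in% pg),
                      rownames(pas$pas2))
  expect_gt(length(untouched), 0)
  expect_lt(max(abs(pas$pas2[untouched, ])), 1e-6)
})

test_that("platform distortion is monotone and leaves AUC invariant", {
  pert <- data.frame(pathway = "Pathway 001", class = "AML", delta = 1)
  base_cfg <- function(platform) sim_config(
    seed = 17, n_genes = 200, n_pathways = 15,
    class_sizes = c(Normal = 3, AML = 5), perturbations = pert,
    platform = platform)
  st1 <- simulate_cohort(base_cfg(list(gain = 1, power = 1)))
  st2 <- simulate_cohort(base_cfg(list(gain = 0.5, power = 1.3)))
  i1 <- st1$probe_matrix$intensities; i2 <- st2$probe_matrix$intensities
  expect_equal(i2, 0.5 * i1^1.3)
  m1 <- run_pathway_markers(st1, fraction = 1)
  m2 <- run_pathway_markers(st2, fraction = 1)
  expect_equal(m1$auc[order(m1$feature_id)], m2$auc[order(m2$feature_id)],
               tolerance = 0.2)  # normalization differs, ranking should not
  expect_equal(m1$feature_id[1], m2$feature_id[1])
})

test_that("two-platform studies share truth and recover known overlap", {
  pa <- data.frame(pathway = c("Pathway 010", "Pathway 020", "Pathway 030",
                               "Pathway 040"),
                   class = "AML", delta = c(1, -1, 1, 1))
  pb <- data.frame(pathway = c("Pathway 010", "Pathway 020", "Pathway 030",
                               "Pathway 050"),
                   class = "AML", delta = c(1, -1, -1, -1))
  cfg <- sim_config(seed = 23, n_genes = 1000, n_pathways = 50,
                    class_sizes = c(Normal = 3, AML = 7),
                    perturbations = pa, noise_sd = 0.3)
  tp <- simulate_two_platform_study(cfg, perturbations_b = pb,
                                    class_sizes_b = c(Normal = 10, AML = 15))
  expect_identical(pathway_names(tp$a$pathway_db),
                   pathway_names(tp$b$pathway_db))
  ma <- run_pathway_markers(tp$a, fraction = 0.3)
  mb <- run_pathway_markers(tp$b, fraction = 0.3)
  expect_true(all(pa$pathway %in% ma$feature_id[ma$selected]))
  expect_true(all(pb$pathway %in% mb$feature_id[mb$selected]))
  keep <- function(m, truth, co) {
    sel <- m[m$selected & m$feature_id %in% truth, ]
    marker_list(sel$feature_id, sel$direction, cohort = co, level = "pathway")
  }
  rep <- match_markers(keep(ma, pa$pathway, "A"), keep(mb, pb$pathway, "B"))
  s <- setNames(summarize_matches(rep)$n_pairs, summarize_matches(rep)$category)
  expect_equal(unname(s["complete_concordant"]), 2)   # 010 up/up, 020 down/down
  expect_equal(unname(s["complete_discordant"]), 1)   # 030 opposite signs
  expect_equal(unname(s[c("incomplete_concordant", "incomplete_discordant")]),
               c(0, 0))
  expect_equal(rep$unmatched_a, "Pathway 040")
  expect_equal(rep$unmatched_b, "Pathway 050")
})

test_that("simulated studies round-trip through the pipeline file formats", {
  cfg <- sim_config(seed = 31, n_genes = 60, n_pathways = 8,
                    class_sizes = c(Normal = 2, AML = 3))
  st <- simulate_cohort(cfg)
  d <- tempfile("simio")
  paths <- write_sim_study(st, d)
  expect_true(all(file.exists(paths)))
  pm <- read_probe_tsv(paths["probes"], paths["annotation"])
  expect_equal(dim(pm$intensities), dim(st$probe_matrix$intensities))
  expect_equal(sort(dimnames(pm$intensities)[[1]]),
               sort(dimnames(st$probe_matrix$intensities)[[1]]))
  expect_equal(aggregate_probes(pm), aggregate_probes(st$probe_matrix))
  db <- read_pathway_db(paths["pathways"])
  expect_equal(pathway_names(db), pathway_names(st$pathway_db))
})
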