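# a tiny two-family fixture across four species used by the rule tests:
# famA occurs (and is expressed) in all four species, famB only in two
make_discovery_fixture <- function(famA_down_in_sp2 = FALSE) {
  species <- paste0("sp", 1:4)
  genes <- list(); fams <- list(); expr <- list(); stw <- list()
  for (sp in species) {
    fam_here <- if (sp %in% c("sp1", "sp2")) c("famA", "famB") else "famA"
    g <- data.frame(gene_id = paste0(sp, "_", fam_here),
                    family_id = fam_here, species = sp,
                    stringsAsFactors = FALSE)
    genes[[sp]] <- g
    fams[[sp]] <- data.frame(family_id = fam_here, species = sp,
                             copy_count = 1, diatom_specific = TRUE,
                             stringsAsFactors = FALSE)
    cnt <- matrix(500, nrow(g), 6,
                  dimnames = list(g$gene_id, paste0(sp, "_s", 1:6)))
    expr[[sp]] <- make_expr(cnt, species = sp, n_sex = 3)
    sig <- data.frame(gene_id = g$gene_id, species = sp, stage = "S",
                      log2fc = 3, p_raw = 1e-6, significant = TRUE,
                      direction = "up", stringsAsFactors = FALSE)
    if (famA_down_in_sp2 && sp == "sp2") {
      sig$log2fc[sig$gene_id == "sp2_famA"] <- -2
      sig$direction[sig$gene_id == "sp2_famA"] <- "down"
    }
    stw[[sp]] <- fake_stagewise(sig)
  }
  list(families = gene_family_table(do.call(rbind, genes),
                                    do.call(rbind, fams)),
       expr = expr, stagewise = stw)
}

test_that("discovery step 1 excludes families expressed in too few species and step 2 punishes downregulation", {
  fx <- make_discovery_fixture()
  cand <- discover_markers(fx$families, fx$stagewise, fx$expr)
  expect_equal(cand$status[cand$family_id == "famB"], "excluded_step1")
  expect_equal(cand$exclusion_step[cand$family_id == "famB"], 1L)
  expect_equal(cand$status[cand$family_id == "famA"], "ranked")
  expect_equal(cand$rank[cand$family_id == "famA"], 1L)
  expect_equal(cand$rank_score[cand$family_id == "famA"], 3)

  fx2 <- make_discovery_fixture(famA_down_in_sp2 = TRUE)
  cand2 <- discover_markers(fx2$families, fx2$stagewise, fx2$expr)
  expect_equal(cand2$status[cand2$family_id == "famA"], "excluded_step2")
  expect_equal(cand2$exclusion_step[cand2$family_id == "famA"], 2L)
  # every excluded family carries a machine-readable step
  expect_true(all(!is.na(cand2$exclusion_step[cand2$status != "ranked"])))
})

test_that("planted families are recovered at the top ranks and ranking is order-invariant", {
  sim <- simulate_multispecies(sim_config(), seed = 3)
  sw <- lapply(names(sim$expr), function(sp)
    de_integrate_species(sim$expr[[sp]], sp))
  names(sw) <- names(sim$expr)
  cand <- discover_markers(sim$families, sw, sim$expr)
  top3 <- cand$family_id[!is.na(cand$rank) & cand$rank <= 3]
  expect_setequal(top3, sim$truth$planted_markers)
  expect_false(any(sim$truth$planted_controls %in% top3))

  # permute genes and samples everywhere: identical ranking
  expr_perm <- lapply(sim$expr, function(x) {
    set.seed(1)
    gi <- sample(nrow(x$counts)); si <- sample(ncol(x$counts))
    expression_matrix(x$counts[gi, si], x$samples[si, ], x$gene_lengths)
  })
  cand2 <- discover_markers(sim$families, sw, expr_perm)
  expect_equal(cand2$family_id[!is.na(cand2$rank)],
               cand$family_id[!is.na(cand$rank)])
})

test_that("atlas specificity keeps clean markers and rejects leaky or flat families", {
  # family with zero atlas expression passes; one with atlas max equal to
  # its sexual mean fails at defaults
  genes <- data.frame(gene_id = c("sp1_clean", "sp1_leaky", "sp1_ballast"),
                      family_id = c("Fclean", "Fleaky", "Fball"),
                      species = "sp1")
  fams <- data.frame(family_id = c("Fclean", "Fleaky", "Fball"),
                     species = "sp1", copy_count = 1,
                     diatom_specific = TRUE)
  ft <- gene_family_table(genes, fams)
  lens <- c(sp1_clean = 1000, sp1_leaky = 1000, sp1_ballast = 1000)
  atlas_cnt <- rbind(sp1_clean = c(0, 0, 0),
                     sp1_leaky = c(400, 400, 400),
                     sp1_ballast = c(1e6, 1e6, 1e6) - 400)
  colnames(atlas_cnt) <- paste0("a", 1:3)
  atlas_meta <- data.frame(sample_id = colnames(atlas_cnt), species = "sp1",
                           condition_class = "atlas", stage = "none",
                           condition_label = "c1", replicate = 1:3)
  atlas <- expression_matrix(atlas_cnt, atlas_meta, lens)
  sex_cnt <- rbind(sp1_clean = c(400, 400), sp1_leaky = c(400, 400),
                   sp1_ballast = c(1e6, 1e6) - 800)
  colnames(sex_cnt) <- paste0("x", 1:2)
  sexual <- make_expr(sex_cnt, n_sex = 2, lengths = lens)
  cand <- data.frame(family_id = c("Fclean", "Fleaky"),
                     status = "ranked", exclusion_step = NA_integer_,
                     n_species_expressed = 4L,
                     rank_score = c(5, 4), rank = 1:2,
                     stringsAsFactors = FALSE)
  class(cand) <- c("marker_candidates", "data.frame")
  sp <- specificity_filter(cand, atlas, sexual, ft)
  expect_true(sp$table$passes[sp$table$family_id == "Fclean"])
  expect_false(sp$table$passes[sp$table$family_id == "Fleaky"])
  expect_equal(sp$selected, "Fclean")
  expect_equal(sp$table$fold_separation[sp$table$family_id == "Fleaky"], 1,
               tolerance = 0.01)

  # a candidate absent from the atlas species is untestable, not passed
  cand3 <- rbind(cand, data.frame(family_id = "Fmissing", status = "ranked",
                                  exclusion_step = NA_integer_,
                                  n_species_expressed = 3L,
                                  rank_score = 3, rank = 3L))
  class(cand3) <- c("marker_candidates", "data.frame")
  sp3 <- specificity_filter(cand3, atlas, sexual, ft)
  row <- sp3$table[sp3$table$family_id == "Fmissing", ]
  expect_false(row$testable)
  expect_false(row$passes)
})

test_that("leaky planted families are excluded from the selected markers", {
  sim <- simulate_multispecies(sim_config(n_planted_markers = 4), seed = 5)
  sw <- lapply(names(sim$expr), function(sp)
    de_integrate_species(sim$expr[[sp]], sp))
  names(sw) <- names(sim$expr)
  cand <- discover_markers(sim$families, sw, sim$expr)
  leaky_fam <- sim$truth$planted_markers[1]
  atlas <- simulate_atlas(sim, sim_config(), seed = 5,
                          leaky = stats::setNames(0.5, leaky_fam))
  sp <- specificity_filter(cand, atlas, sim$expr[[1]], sim$families,
                           k = 3)
  expect_false(leaky_fam %in% sp$selected)
  expect_setequal(sp$selected, setdiff(sim$truth$planted_markers, leaky_fam))
})

test_that("curated marker selection keeps only expressed, significantly upregulated genes", {
  cnt <- rbind(gTrue1 = c(300, 300, 300, 10, 10, 10),
               gTrue2 = c(200, 250, 220, 10, 10, 10),
               gSilent = c(0, 0, 0, 0, 0, 0),
               gFlat = c(50, 60, 55, 50, 60, 55),
               ballast = rep(5000, 6))
  colnames(cnt) <- paste0("s", 1:6)
  x <- make_expr(cnt, species = "sp4", n_sex = 3)
  st <- data.frame(gene_id = c("gTrue1", "gTrue2", "gFlat"),
                   species = "sp4", stage = "S",
                   log2fc = c(4, 4, 0.1), p_raw = c(1e-8, 1e-8, 0.9),
                   significant = c(TRUE, TRUE, FALSE),
                   direction = c("up", "up", "up"))
  candidates <- data.frame(gene_id = c("gTrue1", "gTrue2", "gSilent",
                                       "gFlat"),
                           family_id = c("F1", "F2", "F3", "F4"))
  kept <- select_curated_markers(candidates, fake_stagewise(st), x)
  expect_setequal(kept$gene_id, c("gTrue1", "gTrue2"))
  expect_error(select_curated_markers(candidates[0, ], fake_stagewise(st), x),
               "empty")
})

test_that("control selection enforces eligibility and matches by nearest neighbour", {
  # families F1..F6 single copy in 4 species except: Fdup2 duplicated twice,
  # Fnarrow present in 2 species only, Fup upregulated
  species <- paste0("sp", 1:4)
  fam_def <- list(
    Ftgt = list(copies = c(1, 1, 1, 1)),
    FcandA = list(copies = c(1, 1, 1, 1)),
    FcandB = list(copies = c(1, 2, 1, 1)),   # one duplication: eligible
    Fdup2 = list(copies = c(2, 2, 1, 1)),    # two duplications: ineligible
    Fnarrow = list(copies = c(1, 1, 0, 0)),  # two species: ineligible
    Fup = list(copies = c(1, 1, 1, 1)))      # upregulated: ineligible
  genes <- list(); fams <- list()
  for (f in names(fam_def)) for (i in seq_along(species)) {
    k <- fam_def[[f]]$copies[i]
    if (k == 0) next
    genes[[paste(f, i)]] <- data.frame(
      gene_id = paste0(species[i], "_", f, "_c", seq_len(k)),
      family_id = f, species = species[i], stringsAsFactors = FALSE)
    fams[[paste(f, i)]] <- data.frame(family_id = f, species = species[i],
                                      copy_count = k, diatom_specific = FALSE,
                                      stringsAsFactors = FALSE)
  }
  ft <- gene_family_table(do.call(rbind, genes), do.call(rbind, fams))

  # expression for species 1 only: columns sum to 1e6, lengths 1 kb, so TPM
  # equals the count and the (mean, CV) coordinates are fully controlled
  gsp1 <- ft$genes$gene_id[ft$genes$species == "sp1"]
  tgt_vals <- c(100, 120, 140)           # mean 120
  prof <- list(Ftgt = tgt_vals, FcandA = c(110, 125, 150),
               FcandB = c(500, 600, 700), Fdup2 = c(100, 120, 140),
               Fnarrow = c(100, 120, 140), Fup = c(100, 120, 140))
  cnt <- t(vapply(gsp1, function(g) {
    f <- ft$genes$family_id[ft$genes$gene_id == g]
    prof[[f]]
  }, numeric(3)))
  cnt <- rbind(cnt, ballast = 1e6 - colSums(cnt))
  colnames(cnt) <- paste0("v", 1:3)
  lens <- stats::setNames(rep(1000, nrow(cnt)), rownames(cnt))
  meta <- data.frame(sample_id = colnames(cnt), species = "sp1",
                     condition_class = "vegetative_control", stage = "none",
                     condition_label = "veg", replicate = 1:3)
  x <- expression_matrix(cnt, meta, lens)

  st <- fake_stagewise(data.frame(
    gene_id = "sp1_Fup_c1", species = "sp1", stage = "S", log2fc = 3,
    p_raw = 1e-9, significant = TRUE, direction = "up"))
  panel <- select_control_markers(ft, list(st), list(sp1 = x),
                                  targets = "Ftgt")
  expect_equal(panel$control_family, "FcandA")
  expect_false(any(c("Fdup2", "Fnarrow", "Fup") %in% panel$control_family))

  # brute-force nearest-neighbour on the realized coordinates
  eps <- 1e-6
  stats_of <- function(v) c(mean(v), sd(v) / mean(v))
  tg <- stats_of(tgt_vals)
  dists <- vapply(list(A = prof$FcandA, B = prof$FcandB), function(v) {
    s <- stats_of(v)
    sqrt((log10(s[1] + eps) - log10(tg[1] + eps))^2 + (s[2] - tg[2])^2)
  }, numeric(1))
  expect_equal(panel$control_family, c("FcandA", "FcandB")[which.min(dists)])
  expect_equal(panel$match_distance, unname(min(dists)), tolerance = 1e-6)

  expect_error(select_control_markers(ft, list(st), list(sp1 = x),
                                      targets = c("Ftgt", "FcandA", "FcandB")),
               "eligible")
})
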