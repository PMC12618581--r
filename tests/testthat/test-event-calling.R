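test_that("MAG x sample retention applies the read and gene floors", {
  # three cells: 9,999 reads over 1,200 genes; 10,000 reads over exactly
  # 1,000 genes; 50,000 reads over 999 genes
  e1 <- make_cell_expr("magA", "s1", c(rep(8, 1199), 9999 - 8 * 1199))
  e2 <- make_cell_expr("magA", "s2", rep(10, 1000))
  e3 <- make_cell_expr("magB", "s1", c(rep(50, 999), rep(0, 300)))
  ds <- mag_dataset(rbind(e1, e2, e3),
                    mags = data.frame(mag_id = c("magA", "magB"),
                                      clade = "raphid_pennate",
                                      genus = "G"),
                    samples = data.frame(sample_id = c("s1", "s2"),
                                         station = c("st1", "st2"),
                                         depth = "SRF",
                                         size_fraction = "20-180"))
  flt <- filter_mag_samples(ds)
  get <- function(m, s) flt$keep[flt$mag_id == m & flt$sample_id == s]
  expect_false(get("magA", "s1"))  # 9,999 reads
  expect_true(get("magA", "s2"))   # exactly at both floors
  expect_false(get("magB", "s1"))  # 999 expressed genes
})

test_that("MAG-level TPM is a within-cell composition", {
  e <- make_cell_expr("magA", "s1", c(10, 10), lengths = c(1000, 2000))
  ds <- mag_dataset(e, data.frame(mag_id = "magA", clade = "centric",
                                  genus = "G"),
                    data.frame(sample_id = "s1", station = "st1",
                               depth = "SRF", size_fraction = "20-180"))
  tp <- mag_tpm(ds)
  expect_equal(tp$tpm, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  # doubling all counts leaves TPM unchanged; a single expressed gene gets 1e6
  e2 <- e; e2$count <- e2$count * 2
  ds2 <- ds; ds2$expr <- e2
  expect_equal(mag_tpm(ds2)$tpm, tp$tpm)
  e3 <- make_cell_expr("magA", "s1", c(42, 0))
  ds3 <- ds; ds3$expr <- e3
  expect_equal(mag_tpm(ds3)$tpm, c(1e6, 0))
})

test_that("threshold calibration is the interpolated percentile of pooled vegetative TPM", {
  # one marker gene whose TPM across 100 vegetative samples is exactly 1..100
  cnt <- rbind(mk = 1:100, ballast = 1e6 - (1:100))
  colnames(cnt) <- sprintf("v%03d", 1:100)
  lens <- c(mk = 1000, ballast = 1000)
  meta <- data.frame(sample_id = colnames(cnt), species = "ref",
                     condition_class = "vegetative_control", stage = "none",
                     condition_label = "veg", replicate = 1:100)
  x <- expression_matrix(cnt, meta, lens)
  ft <- gene_family_table(
    data.frame(gene_id = "mk", family_id = "FAM_M", species = "ref"),
    data.frame(family_id = "FAM_M", species = "ref", copy_count = 1,
               diatom_specific = TRUE))
  panel <- marker_panel("M1", "FAM_M", "all_diatoms", positive_control = "M1")
  thr <- calibrate_thresholds(x, panel, ft)
  expect_equal(thr$threshold, 95.05)
  expect_equal(thr$threshold, pct_oracle(1:100, 95))
  expect_equal(thr$n_values, 100L)

  # constant vector gives the constant; random vectors match the oracle
  cnt2 <- rbind(mk = rep(7, 20), ballast = rep(1e6 - 7, 20))
  colnames(cnt2) <- sprintf("w%02d", 1:20)
  meta2 <- meta[1:20, ]; meta2$sample_id <- colnames(cnt2)
  x2 <- expression_matrix(cnt2, meta2, lens)
  expect_equal(calibrate_thresholds(x2, panel, ft)$threshold, 7)

  set.seed(3)
  v <- round(runif(37, 0, 500))
  cnt3 <- rbind(mk = v, ballast = 1e6 - v)
  colnames(cnt3) <- sprintf("u%02d", seq_along(v))
  meta3 <- meta[seq_along(v), ]; meta3$sample_id <- colnames(cnt3)
  x3 <- expression_matrix(cnt3, meta3, lens)
  for (q in c(50, 90, 95, 99))
    expect_equal(
      calibrate_thresholds(x3, panel, ft,
                           analysis_config(percentile_q = q))$threshold,
      pct_oracle(v, q))

  panel_bad <- marker_panel("MX", "FAM_ABSENT", "all_diatoms",
                            positive_control = "MX")
  expect_error(calibrate_thresholds(x, panel_bad, ft), "no member gene")
})

test_that("marker expression requires strict TPM exceedance and two-read support", {
  thr <- data.frame(label = "M1", family_id = "F", threshold = 100,
                    n_values = 10L)
  class(thr) <- c("threshold_table", "data.frame")
  asg <- data.frame(gene_id = "g1", marker_label = "M1")
  cell <- function(tpm, count)
    data.frame(gene_id = "g1", count = count, tpm = tpm)
  expect_false(call_marker_expression(cell(150, 1), asg, thr)[["M1"]])
  expect_false(call_marker_expression(cell(100, 5), asg, thr)[["M1"]])
  expect_true(call_marker_expression(cell(150, 2), asg, thr)[["M1"]])

  # any passing homolog suffices; absent genes count as zero
  asg2 <- data.frame(gene_id = c("g1", "g2"), marker_label = "M1")
  cell2 <- data.frame(gene_id = "g1", count = 0, tpm = 0)
  expect_false(call_marker_expression(cell2, asg2, thr)[["M1"]])
  cell3 <- data.frame(gene_id = c("g1", "g2"), count = c(0, 9),
                      tpm = c(0, 500))
  expect_true(call_marker_expression(cell3, asg2, thr)[["M1"]])
  expect_error(
    call_marker_expression(cell3, data.frame(gene_id = "g1",
                                             marker_label = "M9"), thr),
    "no threshold")
})

test_that("event calling needs the positive control plus enough co-markers", {
  sim <- simulate_mag_dataset(sim_config(n_mags = 6, n_mag_samples = 10),
                              seed = 2)
  thr <- calibrate_thresholds(sim$reference,
                              rbind(sim$panel, sim$control_panel),
                              sim$families)
  calls <- call_events(sim$dataset, sim$assignment, thr, sim$panel)
  expect_true(all(calls$is_event ==
                    (calls$spo11_status & calls$tier >= 2)))
  # tier sweep monotone and nested
  sweep <- tier_sweep(calls)
  expect_true(all(diff(sweep) <= 0))
  for (k in 1:3) {
    ev_hi <- calls$spo11_status & calls$tier >= k + 1
    ev_lo <- calls$spo11_status & calls$tier >= k
    expect_true(all(which(ev_hi) %in% which(ev_lo)))
  }
  # calls match the ground truth on this small run
  tr <- sim$truth
  key <- paste(tr$mag_id, tr$sample_id)
  ck <- paste(calls$mag_id, calls$sample_id)
  called <- calls$is_event[match(key, ck)]
  called[is.na(called)] <- FALSE
  eval_cells <- key %in% ck
  expect_true(all(called[tr$sexual & eval_cells]))
  expect_true(mean(called[!tr$sexual & eval_cells]) <= 0.01)
})

test_that("event calling is invariant to gene order and uniform count rescaling", {
  sim <- simulate_mag_dataset(sim_config(n_mags = 4, n_mag_samples = 6),
                              seed = 4)
  thr <- calibrate_thresholds(sim$reference,
                              rbind(sim$panel, sim$control_panel),
                              sim$families)
  calls <- call_events(sim$dataset, sim$assignment, thr, sim$panel)
  perm <- sim$dataset
  set.seed(1)
  perm$expr <- perm$expr[sample(nrow(perm$expr)), ]
  calls_p <- call_events(perm, sim$assignment, thr, sim$panel)
  ord <- function(d) d[order(d$mag_id, d$sample_id), ]
  expect_equal(ord(calls_p)$passing_markers, ord(calls)$passing_markers)

  resc <- sim$dataset
  one_cell <- resc$expr$mag_id == resc$expr$mag_id[1] &
    resc$expr$sample_id == resc$expr$sample_id[1]
  resc$expr$count[one_cell] <- resc$expr$count[one_cell] * 3
  calls_r <- call_events(resc, sim$assignment, thr, sim$panel)
  expect_equal(ord(calls_r)$tier, ord(calls)$tier)
})

test_that("a MAG of clade 'other' is excluded from calling", {
  sim <- simulate_mag_dataset(sim_config(n_mags = 4, n_mag_samples = 6),
                              seed = 6)
  sim$dataset$mags$clade[1] <- "other"
  thr <- calibrate_thresholds(sim$reference,
                              rbind(sim$panel, sim$control_panel),
                              sim$families)
  calls <- call_events(sim$dataset, sim$assignment, thr, sim$panel)
  expect_false(sim$dataset$mags$mag_id[1] %in% calls$mag_id)
})

test_that("event summaries count cases, stations and MAG fractions", {
  calls <- data.frame(
    mag_id = c("m1", "m1", "m2"), sample_id = c("s1", "s2", "s1"),
    spo11_status = TRUE, passing_markers = "M1,M3", tier = 2,
    is_event = TRUE, panel_used = "raphid_pennate",
    stringsAsFactors = FALSE)
  class(calls) <- c("sex_event_calls", "data.frame")
  ds <- mag_dataset(
    make_cell_expr("m1", "s1", c(10, 10)),
    mags = data.frame(mag_id = paste0("m", 1:4),
                      clade = c("raphid_pennate", "centric",
                                "raphid_pennate", "centric"),
                      genus = paste0("G", 1:4)),
    samples = data.frame(sample_id = paste0("s", 1:5),
                         station = paste0("st", c(1, 2, 3, 4, 5)),
                         depth = "SRF", size_fraction = "20-180"))
  sm <- summarize_events(calls, ds)
  expect_equal(sm$n_cases, 3)
  expect_equal(sm$station_fraction, 2 / 5)
  expect_equal(sm$mag_fraction, 2 / 4)
  expect_equal(unname(sm$cases_by_clade["raphid_pennate"]), 2L)
  expect_equal(unname(sm$cases_by_clade["centric"]), 1L)
  # brute-force case count: one per is_event row
  expect_equal(sm$n_cases, sum(calls$is_event))

  empty <- calls[0, ]
  class(empty) <- c("sex_event_calls", "data.frame")
  sm0 <- summarize_events(empty, ds)
  expect_equal(sm0$n_cases, 0)
  expect_equal(sm0$station_fraction, 0)
  expect_equal(sm0$mag_fraction, 0)
})

test_that("the control audit runs the identical rule on the control panel", {
  sim <- simulate_mag_dataset(sim_config(n_mags = 6, n_mag_samples = 10),
                              seed = 8, planted_frac = 0)
  thr <- calibrate_thresholds(sim$reference,
                              rbind(sim$panel, sim$control_panel),
                              sim$families)
  aud <- audit_controls(sim$dataset, sim$control_assignment, thr,
                        sim$control_panel)
  expect_equal(aud$n_cases, sum(aud$calls$is_event))
  expect_true(all(aud$calls$is_event ==
                    (aud$calls$spo11_status & aud$calls$tier >= 2)))
  # a single crafted cell with PC + C1 + C2 passing is one case
  thr2 <- data.frame(label = c("PC", "C1", "C2", "C3", "C4"),
                     family_id = paste0("F", 1:5),
                     threshold = 10, n_values = 10L)
  class(thr2) <- c("threshold_table", "data.frame")
  cellg <- c("PC", "C1", "C2", "C3", "C4")
  e <- rbind(
    data.frame(mag_id = "magZ", sample_id = "sz",
               gene_id = paste0("magZ_", cellg),
               count = c(50, 50, 50, 0, 0), length = 1000),
    make_cell_expr("magZ", "sz", rep(12, 1000)))
  ds <- mag_dataset(e, data.frame(mag_id = "magZ", clade = "centric",
                                  genus = "G"),
                    data.frame(sample_id = "sz", station = "st1",
                               depth = "SRF", size_fraction = "20-180"))
  asg <- data.frame(mag_id = "magZ", gene_id = paste0("magZ_", cellg),
                    marker_label = cellg)
  pan <- marker_panel(cellg, paste0("F", 1:5), rep("all_diatoms", 5),
                      positive_control = "PC")
  aud2 <- audit_controls(ds, asg, thr2, pan)
  expect_equal(aud2$n_cases, 1)
  expect_equal(aud2$calls$tier, 2)
})
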