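test_that("lattice handles the degenerate 1x1 case and is deterministic", {
  cfg <- sim_config(n_cols = 1, n_rows = 1, cell_pitch_px = 30, jitter = 0)
  cm <- build_cell_lattice(cfg)
  expect_equal(nrow(cm$cells), 1L)
  expect_true(all(cm$label_image == 1L))
  expect_equal(cm$cells$area_px, cm$width * cm$height)

  cfg2 <- sim_config(n_cols = 6, n_rows = 5, cell_pitch_px = 14, jitter = 0.3,
                     seed = 42)
  cm_a <- build_cell_lattice(cfg2)
  cm_b <- build_cell_lattice(cfg2)
  expect_identical(cm_a$label_image, cm_b$label_image)
  expect_identical(cm_a$cells, cm_b$cells)
})

test_that("regular lattice tiles the strip with equal interior cells", {
  cfg <- sim_config(n_cols = 10, n_rows = 10, cell_pitch_px = 36, jitter = 0)
  cm <- build_cell_lattice(cfg)
  expect_equal(nrow(cm$cells), 100L)
  # every pixel belongs to exactly one cell
  expect_true(all(cm$label_image >= 1L))
  expect_equal(sum(cm$cells$area_px), cm$width * cm$height)
  # labels contiguous from 1
  expect_identical(sort(unique(as.vector(cm$label_image))), 1:100)
  # interior cells of the regular tiling share the same area to within 1%
  # (cells clipped by the strip boundary necessarily differ)
  interior <- cm$cells$area_px[!cm$cells$border]
  expect_gt(length(interior), 50)
  expect_lt(diff(range(interior)) / mean(interior), 0.01)
})

test_that("domain assignment enforces rho within mir9a, half-open intervals", {
  cfg <- sim_config(n_cols = 4, n_rows = 20, cell_pitch_px = 8,
                    domain_spec = list(rho = c(0.3, 0.6), mir9a = c(0.25, 0.6)))
  cm <- build_cell_lattice(cfg)
  fl <- assign_domains(cm, cfg)
  expect_true(all(fl$mir9a[fl$rho]))            # containment
  only_mir <- fl$mir9a & !fl$rho
  expect_gt(sum(only_mir), 0)                   # ventral mir9a-only band
  dv <- cm$cells$dv[only_mir]
  expect_true(all(dv >= 0.25 & dv < 0.3))

  cfg_eq <- sim_config(n_cols = 4, n_rows = 20, cell_pitch_px = 8,
                       domain_spec = list(rho = c(0.3, 0.6), mir9a = c(0.3, 0.6)))
  fl_eq <- assign_domains(cm, cfg_eq)
  expect_identical(fl_eq$rho, fl_eq$mir9a)

  cfg_empty <- sim_config(n_cols = 4, n_rows = 20, cell_pitch_px = 8,
                          domain_spec = list(rho = c(0.5, 0.5), mir9a = c(0.5, 0.5)))
  fl_empty <- assign_domains(cm, cfg_empty)
  expect_equal(sum(fl_empty$rho), 0L)

  expect_error(sim_config(domain_spec = list(rho = c(0.2, 0.7),
                                             mir9a = c(0.25, 0.7))),
               "contained")
})

test_that("transcription simulation matches telegraph stationary moments", {
  cfg <- counts_config(seed = 11)
  cm <- build_cell_lattice(cfg)
  fl <- assign_domains(cm, cfg)
  gt <- simulate_transcription(cm, fl, cfg, "WT")
  x <- gt$cells$true_mrna
  expect_gte(length(x), 500)

  m_th <- oracle_telegraph_mean(cfg, cfg$k_deg_wt)
  v_th <- oracle_telegraph_var(cfg, cfg$k_deg_wt)
  expect_lt(abs(mean(x) - m_th), 3 * sd(x) / sqrt(length(x)))
  expect_lt(abs(var(x) - v_th), 3 * se_of_variance(x))

  # TS states bounded by allele number; reproducible under the same seed
  expect_true(all(gt$cells$true_ts <= cfg$n_alleles))
  gt2 <- simulate_transcription(cm, fl, cfg, "WT")
  expect_identical(gt, gt2)
})

test_that("KO slows decay: mean counts scale by ko_deg_factor", {
  cfg <- counts_config(ko_deg_factor = 2, seed = 12)
  cm <- build_cell_lattice(cfg)
  fl <- assign_domains(cm, cfg)
  wt <- simulate_transcription(cm, fl, cfg, "WT")$cells$true_mrna
  ko <- simulate_transcription(cm, fl, cfg, "KO")$cells$true_mrna
  r <- mean(ko) / mean(wt)
  se_r <- r * sqrt(var(wt) / (length(wt) * mean(wt)^2) +
                   var(ko) / (length(ko) * mean(ko)^2))
  expect_lt(abs(r - 2), 3 * se_r)
})

test_that("zero transcription rate gives empty cells and no TS", {
  cfg <- counts_config(k_tx = 0)
  cm <- build_cell_lattice(cfg)
  fl <- assign_domains(cm, cfg)
  gt <- simulate_transcription(cm, fl, cfg, "WT")
  expect_true(all(gt$cells$true_mrna == 0L))
})

test_that("leaky transcription outside the domain is rare and TS-free", {
  cfg <- sim_config(n_cols = 20, n_rows = 20, cell_pitch_px = 8,
                    domain_spec = list(rho = c(0.4, 0.6), mir9a = c(0.3, 0.6)))
  cm <- build_cell_lattice(cfg)
  fl <- assign_domains(cm, cfg)
  gt <- simulate_transcription(cm, fl, cfg, "WT")
  off <- gt$cells$true_mrna[!fl$rho]
  expect_true(all(gt$cells$true_ts[!fl$rho] == 0L))
  # leak mean = n_alleles * leak_frac * k_tx / k_deg, far below the filter
  lam <- cfg$n_alleles * cfg$leak_frac * cfg$k_tx / cfg$k_deg_wt
  expect_lt(mean(off), lam + 3 * sqrt(lam / length(off)))
  expect_lt(mean(off >= 10), 0.01)
})

test_that("protein model: zero before onset, steady state, KO precedence", {
  cfg <- sim_config(n_cols = 4, n_rows = 10, cell_pitch_px = 10)
  cm <- build_cell_lattice(cfg)
  fl <- assign_domains(cm, cfg)
  early <- simulate_protein(cm, fl, cfg, "WT", t_query = cfg$protein_onset_wt - 1)
  expect_true(all(early$protein == 0))

  # t -> infinity limit equals k_translate * mean mRNA / k_pdeg within 1%
  late <- simulate_protein(cm, fl, cfg, "KO", t_query = 1e6)
  mbar <- oracle_telegraph_mean(cfg, cfg$k_deg_wt / cfg$ko_deg_factor)
  lim <- cfg$k_translate * mbar / cfg$k_pdeg
  expect_lt(abs(max(late$protein) - lim) / lim, 0.01)

  # between the onsets: KO expresses, WT does not, in rho-active cells
  t_mid <- (cfg$protein_onset_ko + cfg$protein_onset_wt) / 2
  p_wt <- simulate_protein(cm, fl, cfg, "WT", t_mid)
  p_ko <- simulate_protein(cm, fl, cfg, "KO", t_mid)
  expect_true(all(p_wt$protein == 0))
  expect_true(all(p_ko$protein[fl$rho] > 0))
  expect_true(all(p_ko$protein[!fl$rho] == 0))
})

test_that("rendering: background-only image, Gaussian integral, intron placement", {
  # zero molecules: mean pixel value within 3 SE of the background
  cfg0 <- sim_config(n_cols = 2, n_rows = 2, cell_pitch_px = 20, k_tx = 0,
                     noise_sd = 4, background_mean = 120)
  cm0 <- build_cell_lattice(cfg0)
  fl0 <- assign_domains(cm0, cfg0)
  gt0 <- simulate_transcription(cm0, fl0, cfg0, "WT")
  rn0 <- render_channels(cm0, gt0, cfg0)
  px <- rn0$images$exon
  expect_lt(abs(mean(px) - 120), 3 * 4 / sqrt(length(px)))

  # one noiseless mRNA: integrated excess intensity = amp * 2*pi*sigma^2 to 1%
  cfg1 <- sim_config(n_cols = 1, n_rows = 1, cell_pitch_px = 60, noise_sd = 0,
                     margin_px = 10, psf_sigma_px = 1.4, spot_amp = 50)
  cm1 <- build_cell_lattice(cfg1)
  gt1 <- manual_ground_truth(n_mrna = 1L)
  rn1 <- render_channels(cm1, gt1, cfg1)
  integ <- sum(rn1$images$exon - cfg1$background_mean)
  expect_lt(abs(integ - 50 * 2 * pi * 1.4^2) / (50 * 2 * pi * 1.4^2), 0.01)

  # intron-channel spots lie only inside nucleus disks
  cfg2 <- sim_config(n_cols = 5, n_rows = 4, cell_pitch_px = 24, noise_sd = 0)
  cm2 <- build_cell_lattice(cfg2)
  fl2 <- assign_domains(cm2, cfg2)
  gt2 <- simulate_transcription(cm2, fl2, cfg2, "WT")
  rn2 <- render_channels(cm2, gt2, cfg2)
  it <- rn2$spots[rn2$spots$channel == "intron", ]
  expect_gt(nrow(it), 0)
  expect_true(all(rn2$nuclei_mask[cbind(round(it$y), round(it$x))]))
  # exon-channel truth: one spot per mature mRNA plus one per active TS
  n_ts <- sum(gt2$cells$true_ts)
  expect_equal(sum(rn2$spots$channel == "exon"),
               sum(gt2$cells$true_mrna) + n_ts)
})

test_that("TIFF and CSV round trips preserve the embryo", {
  cfg <- sim_config(n_cols = 3, n_rows = 3, cell_pitch_px = 16, seed = 5)
  emb <- simulate_embryo(cfg, "KO", render = TRUE)
  tf <- tempfile(fileext = ".tif")
  write_embryo_tiff(emb$render$images, tf)
  back <- read_embryo_tiff(tf)
  expect_named(back, c("exon", "intron", "membrane", "nuclei"))
  # 16-bit quantization: at most one grey level
  expect_lt(max(abs(back$exon - pmin(pmax(emb$render$images$exon, 0), 65535))),
            1.01)
  td <- tempfile()
  write_embryo_csv(emb, td)
  cells <- read_cell_table(file.path(td, "cells.csv"),
                           required = c("label", "true_mrna", "true_ts"))
  expect_equal(nrow(cells), 9L)
  expect_equal(cells$true_mrna, emb$ground_truth$cells$true_mrna)
  unlink(td, recursive = TRUE); unlink(tf)
})

test_that("configuration validation rejects out-of-range values", {
  expect_error(sim_config(jitter = 0.6), "jitter")
  expect_error(sim_config(n_alleles = 3), "n_alleles")
  expect_error(sim_config(k_on = -1), "negative")
  expect_error(sim_config(k_tx = NaN), "non-finite")
  cfg <- sim_config(n_cols = 2, n_rows = 2)
  tf <- tempfile(fileext = ".yml")
  write_sim_config(cfg, tf)
  expect_equal(read_sim_config(tf), cfg)
  unlink(tf)
})
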