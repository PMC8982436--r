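#' Simulation configuration for synthetic embryos
#'
#' Bundles every parameter of the synthetic-embryo generator: tissue geometry,
#' expression domains along the dorsoventral (DV) axis, telegraph-model
#' transcription kinetics, genotype contrast, protein kinetics, and the camera
#' model used to render images.
#'
#' The kinetic defaults are illustrative, not fitted: they are chosen so that
#' wild-type cells carry a stationary mean of ~50 mRNAs (order of magnitude of
#' published per-cell smFISH counts in the early fly ectoderm) while keeping
#' single molecules optically resolvable at the default cell size
#' (`cell_pitch_px = 96`, i.e. ~10 micron cells at a 100x pixel scale).
#'
#' @param n_cols,n_rows cell-lattice dimensions (columns run along the
#'   anteroposterior axis, rows along the DV axis).
#' @param jitter cell-center displacement as a fraction of `cell_pitch_px`,
#'   in `[0, 0.5)`. 0 gives a regular staggered hexagonal lattice.
#' @param cell_pitch_px center-to-center cell spacing in pixels.
#' @param domain_spec named list of DV on/off intervals in normalized
#'   coordinate `[0,1]`, one per gene; must contain `rho` and `mir9a`, and the
#'   `rho` interval must be contained in the `mir9a` interval (the biological
#'   nesting of the two expression domains).
#' @param k_on,k_off promoter ON/OFF switching rates (1/min).
#' @param k_tx transcription rate while ON (mRNA/min/allele).
#' @param k_deg_wt mRNA degradation rate in wild type (1/min).
#' @param ko_deg_factor multiplicative slowdown of degradation in the miRNA
#'   knockout (KO) genotype; `> 1` means slower decay, hence higher counts.
#' @param n_alleles alleles per cell, 2 (pre-replication) or 4 (post).
#' @param leak_frac basal transcription in domain-inactive cells, as a
#'   fraction of `k_tx` (leaky firing; such cells never show a transcription
#'   site).
#' @param t_end simulated time (min).
#' @param protein_onset_wt,protein_onset_ko time (min) at which translation
#'   starts in each genotype; the KO onset precedes the WT onset by default.
#' @param k_translate protein synthesis rate (protein/mRNA/min).
#' @param k_pdeg protein degradation rate (1/min).
#' @param nascent_mean mean nascent-transcript load at an active
#'   transcription site (the rendered TS amplitude scales with the load).
#' @param psf_sigma_px Gaussian PSF sigma in pixels.
#' @param spot_amp peak amplitude of a single-mRNA spot (camera units).
#' @param ts_amp_scale TS amplitude per unit nascent load, relative to
#'   `spot_amp`.
#' @param nucleus_radius_frac nucleus disk radius as fraction of pitch.
#' @param membrane_amp,nuclei_amp rendered amplitudes of the membrane and
#'   nuclei channels.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param background_mean constant camera background offset.
#' @param margin_px minimum distance (px) of rendered mRNA spots from the
#'   cell boundary.
#' @param min_sep_px minimum pairwise distance (px) between rendered spots in
#'   a cell; 0 disables the constraint (fully uniform placement). Use a value
#'   of ~4 PSF sigma to render the "well-separated" validation regime.
#' @param seed top-level RNG seed; all internal streams derive from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_cols = 4, n_rows = 4)
#' cfg$k_tx
#' @export
sim_config <- function(n_cols = 16, n_rows = 10,
                       jitter = 0.15, cell_pitch_px = 96,
                       domain_spec = list(rho = c(0.3, 0.7), mir9a = c(0.2, 0.7)),
                       k_on = 1, k_off = 0.5, k_tx = 1.875, k_deg_wt = 0.05,
                       ko_deg_factor = 1.5, n_alleles = 2, leak_frac = 0.02,
                       t_end = 200,
                       protein_onset_wt = 300, protein_onset_ko = 60,
                       k_translate = 0.5, k_pdeg = 0.02,
                       nascent_mean = 2,
                       psf_sigma_px = 1.1, spot_amp = 40, ts_amp_scale = 1,
                       nucleus_radius_frac = 0.22,
                       membrane_amp = 150, nuclei_amp = 80,
                       noise_sd = 5, background_mean = 100,
                       margin_px = 1, min_sep_px = 0,
                       seed = 1L) {
  cfg <- list(
    n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
    jitter = jitter, cell_pitch_px = cell_pitch_px,
    domain_spec = lapply(domain_spec, as.numeric),
    k_on = k_on, k_off = k_off, k_tx = k_tx, k_deg_wt = k_deg_wt,
    ko_deg_factor = ko_deg_factor, n_alleles = as.integer(n_alleles),
    leak_frac = leak_frac, t_end = t_end,
    protein_onset_wt = protein_onset_wt, protein_onset_ko = protein_onset_ko,
    k_translate = k_translate, k_pdeg = k_pdeg,
    nascent_mean = nascent_mean,
    psf_sigma_px = psf_sigma_px, spot_amp = spot_amp,
    ts_amp_scale = ts_amp_scale,
    nucleus_radius_frac = nucleus_radius_frac,
    membrane_amp = membrane_amp, nuclei_amp = nuclei_amp,
    noise_sd = noise_sd, background_mean = background_mean,
    margin_px = margin_px, min_sep_px = min_sep_px,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks finiteness, sign and range constraints on every field, including the
#' nesting of the `rho` expression interval inside the `mir9a` interval.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly, or an error describing the violated constraint.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  num <- unlist(cfg[setdiff(names(cfg), "domain_spec")])
  if (any(!is.finite(num))) stop("configuration error: non-finite parameter value")
  rates <- c("k_on", "k_off", "k_tx", "k_deg_wt", "leak_frac", "k_translate",
             "k_pdeg", "noise_sd", "background_mean", "spot_amp",
             "ts_amp_scale", "membrane_amp", "nuclei_amp", "nascent_mean")
  bad <- rates[vapply(rates, function(r) cfg[[r]] < 0, logical(1))]
  if (length(bad)) stop("configuration error: negative rate(s): ",
                        paste(bad, collapse = ", "))
  if (cfg$n_cols < 1L || cfg$n_rows < 1L)
    stop("configuration error: lattice must have at least one cell")
  if (cfg$jitter < 0 || cfg$jitter >= 0.5)
    stop("configuration error: jitter must be in [0, 0.5)")
  if (!cfg$n_alleles %in% c(2L, 4L))
    stop("configuration error: n_alleles must be 2 or 4")
  if (cfg$ko_deg_factor <= 0)
    stop("configuration error: ko_deg_factor must be positive")
  if (cfg$cell_pitch_px <= 0 || cfg$psf_sigma_px <= 0)
    stop("configuration error: pitch and PSF sigma must be positive")
  ds <- cfg$domain_spec
  if (!all(c("rho", "mir9a") %in% names(ds)))
    stop("configuration error: domain_spec needs 'rho' and 'mir9a' intervals")
  for (g in names(ds)) {
    iv <- ds[[g]]
    if (length(iv) != 2L || any(!is.finite(iv)) || iv[1] > iv[2] ||
        iv[1] < 0 || iv[2] > 1)
      stop("configuration error: invalid domain interval for '", g, "'")
  }
  if (ds$rho[1] < ds$mir9a[1] || ds$rho[2] > ds$mir9a[2])
    stop("configuration error: rho interval must be contained in the mir9a interval")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cols, "x", x$n_rows, "cells, pitch",
      x$cell_pitch_px, "px\n")
  cat("  telegraph: k_on", x$k_on, "k_off", x$k_off, "k_tx", x$k_tx,
      "k_deg_wt", x$k_deg_wt, "(KO factor", x$ko_deg_factor, ")\n")
  m <- telegraph_mean(x, "WT")
  cat("  WT stationary mean mRNA/cell:", round(m, 1), "\n")
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `read_sim_config` returns a validated `sim_config`;
#'   `write_sim_config` returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw)
}

#' Closed-form stationary moments of the telegraph model
#'
#' For a two-state promoter (ON/OFF at rates `k_on`/`k_off`), transcription at
#' `k_tx` while ON and first-order decay at `k_deg`, the stationary per-cell
#' moments over `n_alleles` independent alleles are
#' \deqn{E[m] = n_a \, \frac{k_{on}}{k_{on}+k_{off}} \, \frac{k_{tx}}{k_{deg}}}
#' \deqn{Var[m] = E[m]\left(1 + \frac{k_{tx} k_{off}}{(k_{on}+k_{off})(k_{on}+k_{off}+k_{deg})}\right)}
#'
#' @param config a `sim_config`.
#' @param genotype `"WT"` or `"KO"` (KO slows decay by `ko_deg_factor`).
#' @return `telegraph_mean`/`telegraph_variance`: a single number.
#' @export
telegraph_mean <- function(config, genotype = c("WT", "KO")) {
  genotype <- match.arg(genotype)
  k_deg <- genotype_k_deg(config, genotype)
  if (config$k_on + config$k_off == 0 || k_deg == 0) return(NA_real_)
  p_on <- config$k_on / (config$k_on + config$k_off)
  config$n_alleles * p_on * config$k_tx / k_deg
}

#' @rdname telegraph_mean
#' @export
telegraph_variance <- function(config, genotype = c("WT", "KO")) {
  genotype <- match.arg(genotype)
  k_deg <- genotype_k_deg(config, genotype)
  m <- telegraph_mean(config, genotype)
  ks <- config$k_on + config$k_off
  m * (1 + config$k_tx * config$k_off / (ks * (ks + k_deg)))
}

# internal: genotype-resolved degradation rate
genotype_k_deg <- function(config, genotype) {
  if (genotype == "KO") config$k_deg_wt / config$ko_deg_factor else config$k_deg_wt
}
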