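#' Simulate one synthetic embryo
#'
#' Convenience wrapper chaining lattice construction, domain assignment,
#' transcription simulation and (optionally) channel rendering for a single
#' embryo of a given genotype.
#'
#' @param config a [sim_config()].
#' @param genotype `"WT"` or `"KO"`.
#' @param embryo_id identifier carried through the tables.
#' @param seed embryo-level seed (default `config$seed`); distinct embryos
#'   should use distinct seeds.
#' @param render render the image channels (`TRUE`) or stop at ground-truth
#'   tables (`FALSE`).
#' @return list `(cellmap, flags, ground_truth, protein, render)`; `render`
#'   is `NULL` when `render = FALSE`.
#' @export
simulate_embryo <- function(config, genotype = c("WT", "KO"),
                            embryo_id = "e1", seed = config$seed,
                            render = TRUE) {
  genotype <- match.arg(genotype)
  cellmap <- build_cell_lattice(config)
  flags <- assign_domains(cellmap, config)
  gt <- simulate_transcription(cellmap, flags, config, genotype, seed = seed)
  protein <- simulate_protein(cellmap, flags, config, genotype,
                              t_query = config$t_end)
  rnd <- if (render) render_channels(cellmap, gt, config, seed = seed) else NULL
  list(cellmap = cellmap, flags = flags, ground_truth = gt,
       protein = protein, render = rnd, genotype = genotype,
       embryo_id = embryo_id)
}

#' Write / read ground-truth and measured cell tables as CSV
#'
#' `write_embryo_csv` writes `cells.csv`
#' (`label, cx, cy, area_px, dv, genotype, true_mrna, true_ts, true_protein`)
#' and, when the embryo was rendered, `spots.csv`
#' (`x, y, channel, amplitude, cell_label`). `read_cell_table` validates
#' that a CSV carries the requested schema columns; unknown columns are
#' preserved.
#'
#' @param embryo output of [simulate_embryo()].
#' @param dir output directory (created if missing).
#' @return `write_embryo_csv`: the directory, invisibly.
#' @export
write_embryo_csv <- function(embryo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- embryo$cellmap$cells
  gt <- embryo$ground_truth$cells
  cells <- data.frame(label = cm$label, cx = cm$cx, cy = cm$cy,
                      area_px = cm$area_px, dv = cm$dv,
                      genotype = embryo$genotype,
                      true_mrna = gt$true_mrna[match(cm$label, gt$label)],
                      true_ts = gt$true_ts[match(cm$label, gt$label)],
                      true_protein = embryo$protein$protein[
                        match(cm$label, embryo$protein$label)])
  write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  if (!is.null(embryo$render)) {
    sp <- embryo$render$spots
    write.csv(sp[, c("x", "y", "channel", "amplitude", "cell_label")],
              file.path(dir, "spots.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_embryo_csv
#' @param path CSV path.
#' @param required character vector of columns that must be present.
#' @export
read_cell_table <- function(path, required = c("label", "mrna_count")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cell table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Run the replicated mRNA-count experiment
#'
#' Emulates the replicated smFISH count comparison: per replicate
#' experiment, `n_embryos` embryos per genotype are simulated (each with its
#' own derived seed), quantified, filtered (default: drop cells with fewer
#' than 10 mRNAs), subgrouped by transcription-site class, scored for
#' neighbor-cluster dispersion, and compared between genotypes on per-cell
#' counts and Fano factors (pooled over embryos).
#'
#' With `imaging = FALSE` (default) quantification uses the ground-truth
#' counts directly — the count-level pipeline used for replicated
#' calibration experiments. With `imaging = TRUE` each embryo is rendered
#' and pushed through segmentation, spot detection and TS calling.
#'
#' @param config a [sim_config()].
#' @param n_embryos embryos per genotype per replicate (default 3).
#' @param n_replicates independent replicate experiments (default 2),
#'   modelled as independent seed sets.
#' @param seed top-level experiment seed (default `config$seed`).
#' @param min_count low-expression filter threshold.
#' @param imaging run the full imaging pipeline (see Details).
#' @return list with `cells` (all embryos pooled, filtered),
#'   `dispersion` (per focal cell), `comparisons`
#'   (`counts` and `fano`, each a [compare_genotypes()] result),
#'   `ts_class_sizes` (per genotype), `per_embryo` summary, and `recolor`
#'   (label-indexed count/Fano tables per embryo, for recoloring label
#'   images).
#' @export
run_experiment_counts <- function(config, n_embryos = 3L, n_replicates = 2L,
                                  seed = config$seed, min_count = 10L,
                                  imaging = FALSE) {
  validate_sim_config(config)
  all_cells <- list(); all_disp <- list(); per_embryo <- list()
  recolor <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (g in c("WT", "KO")) {
      for (e in seq_len(n_embryos)) {
        eseed <- derive_seed(seed, rep_i, match(g, c("WT", "KO")), e)
        eid <- sprintf("r%d_%s_e%d", rep_i, g, e)
        emb <- simulate_embryo(config, g, embryo_id = eid, seed = eseed,
                               render = imaging)
        if (imaging) {
          q <- quantify_embryo(emb$render$images, config$psf_sigma_px,
                               labels = emb$cellmap$label_image,
                               nuclei_mask = emb$render$nuclei_mask,
                               genotype = g, embryo_id = eid)
          cells <- q$cells
        } else {
          cm <- emb$cellmap$cells
          gt <- emb$ground_truth$cells
          cells <- data.frame(label = cm$label, cx = cm$cx, cy = cm$cy,
                              area_px = cm$area_px,
                              mrna_count = gt$true_mrna,
                              ts_count = gt$true_ts,
                              genotype = g, embryo_id = eid,
                              border = cm$border)
        }
        graph <- build_neighbor_graph(emb$cellmap$label_image)
        disp <- local_dispersion(cells, graph)
        disp$genotype <- g; disp$embryo_id <- eid
        kept <- filter_low_expression(cells, min_count)
        all_cells[[eid]] <- kept
        all_disp[[eid]] <- disp
        recolor[[eid]] <- merge(cells[, c("label", "mrna_count")],
                                disp[, c("label", "fano", "cv")],
                                by = "label", all.x = TRUE)
        per_embryo[[eid]] <- data.frame(
          embryo_id = eid, replicate = rep_i, genotype = g,
          n_cells = nrow(cells), n_kept = nrow(kept),
          mean_count = mean(kept$mrna_count),
          median_count = median(kept$mrna_count),
          mean_fano = mean(disp$fano, na.rm = TRUE))
      }
    }
  }
  cells <- do.call(rbind, all_cells)
  disp <- do.call(rbind, all_disp)
  cmp_counts <- compare_genotypes(cells$mrna_count[cells$genotype == "WT"],
                                  cells$mrna_count[cells$genotype == "KO"],
                                  "counts")
  cmp_fano <- compare_genotypes(disp$fano[disp$genotype == "WT"],
                                disp$fano[disp$genotype == "KO"], "fano")
  ts_sizes <- lapply(split(cells, cells$genotype),
                     function(d) attr(group_by_ts(d), "sizes"))
  list(cells = cells, dispersion = disp,
       comparisons = list(counts = cmp_counts, fano = cmp_fano),
       ts_class_sizes = ts_sizes,
       per_embryo = do.call(rbind, per_embryo), recolor = recolor)
}

#' Run the protein-fluorescence experiment
#'
#' Emulates the immunofluorescence comparison: per genotype, `n_embryos`
#' embryos are simulated at two time points (an early one between the KO
#' and WT protein onsets, and a late one after both), the protein channel
#' is rendered, 15 square ROIs per embryo (5 anterior / 5 central /
#' 5 posterior) are sampled inside the rho expression band (measurement
#' follows the expression border, where the protein signal lives), each
#' ROI's integrated
#' density is background-adjusted, and genotypes are compared per time
#' point. Log10 values are attached for reporting only — the adjustment is
#' always computed on the linear scale, and non-positive adjusted values
#' become `NA` on the log scale (flagged, dropped from plots only).
#'
#' @param config a [sim_config()].
#' @param n_embryos embryos per genotype (default 3).
#' @param t_early,t_late query times (min); defaults are the midpoint of
#'   the two onsets and twice the late onset.
#' @param box_px ROI side length.
#' @param seed top-level seed.
#' @return list with `measurements` (one row per ROI:
#'   `embryo_id, genotype, time, region, integrated_density, area,
#'   background_mean, adjusted, log10_adjusted`) and `comparisons` (per
#'   time point).
#' @export
run_experiment_protein <- function(config, n_embryos = 3L,
                                   t_early = NULL, t_late = NULL,
                                   box_px = 10L, seed = config$seed) {
  validate_sim_config(config)
  if (is.null(t_early))
    t_early <- (config$protein_onset_ko + config$protein_onset_wt) / 2
  if (is.null(t_late))
    t_late <- 2 * max(config$protein_onset_ko, config$protein_onset_wt)
  rows <- list()
  for (g in c("WT", "KO")) for (e in seq_len(n_embryos)) {
    eseed <- derive_seed(seed, 17L, match(g, c("WT", "KO")), e)
    eid <- sprintf("%s_e%d", g, e)
    cellmap <- build_cell_lattice(config)
    flags <- assign_domains(cellmap, config)
    rho_labels <- flags$label[flags$rho]
    for (tq in c(early = t_early, late = t_late)) {
      prot <- simulate_protein(cellmap, flags, config, g, tq)
      pr <- render_protein_image(cellmap, prot, config,
                                 seed = derive_seed(eseed, round(tq)))
      # measure along the expression band: ROIs restricted to rho-domain cells
      band_mask <- pr$tissue_mask
      band_mask[band_mask] <- as.vector(cellmap$label_image)[
        as.vector(cellmap$label_image) > 0] %in% rho_labels
      # background mean over the whole off-tissue region: the limiting case
      # of repeated background measurements, so per-embryo background error
      # stays negligible against ROI-level noise
      background_mean <- mean(pr$image[!pr$tissue_mask])
      rois <- sample_measurement_areas(band_mask, n_per_region = 5L,
                                       regions = 3L, box_px = box_px,
                                       seed = derive_seed(eseed, 3L, round(tq)))
      m <- measure_rois(pr$image, rois)
      adj <- adjusted_fluorescence(m$integrated_density, m$area,
                                   background_mean)
      rows[[paste(eid, tq)]] <- data.frame(
        embryo_id = eid, genotype = g,
        time = if (tq == t_early) "early" else "late",
        region = m$region, integrated_density = m$integrated_density,
        area = m$area, background_mean = background_mean,
        adjusted = as.numeric(adj),
        log10_adjusted = {
          la <- rep(NA_real_, length(adj))
          pos <- as.numeric(adj) > 0
          la[pos] <- log10(as.numeric(adj)[pos])
          la
        })
    }
  }
  meas <- do.call(rbind, rows)
  cmp <- lapply(split(meas, meas$time), function(d)
    compare_genotypes(d$adjusted[d$genotype == "WT"],
                      d$adjusted[d$genotype == "KO"], "counts"))
  list(measurements = meas, comparisons = cmp,
       t_early = t_early, t_late = t_late)
}

#' Build a run manifest
#'
#' Records the configuration hash, seed, package version and per-stage
#' input/output paths of a pipeline run, so a run can be reproduced and its
#' outputs checked.
#'
#' @param config a [sim_config()].
#' @param seed the seed the run used.
#' @param stages named list/character of stage descriptions or paths.
#' @return list of class `run_manifest`.
#' @export
make_manifest <- function(config, seed, stages = list()) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_sim_config(config, tmp)
  structure(list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = as.integer(seed),
    version = as.character(utils::packageVersion("embryoquant")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = stages), class = "run_manifest")
}

#' @rdname make_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
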