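#' Simulate bursty transcription per cell and allele
#'
#' Runs an exact event-driven (Gillespie) simulation of the telegraph model
#' independently for each allele of each cell: the promoter switches
#' OFF<->ON at rates `k_on`/`k_off`, produces mRNA at `k_tx` while ON, and
#' transcripts decay first-order at the genotype's degradation rate
#' (`k_deg_wt`, divided by `ko_deg_factor` for the KO). Promoters start in
#' their stationary ON probability `k_on/(k_on+k_off)` and mRNA at zero; at
#' the default `t_end` the count distribution is at stationarity to within
#' `exp(-k_deg * t_end)`.
#'
#' A transcription site (TS) is an allele whose promoter is ON at `t_end`;
#' its nascent load is drawn as `1 + Poisson(nascent_mean - 1)`. Cells
#' outside the gene's expression domain fire leakily: constitutive
#' Poisson birth-death at `leak_frac * k_tx` per allele, with no TS (leak is
#' modelled as instantaneous firing with no stable ON state).
#'
#' Each cell consumes its own RNG stream derived from `seed` and the cell
#' label, so results do not depend on iteration order or on how many other
#' cells are simulated.
#'
#' @param cellmap a `cell_map` from [build_cell_lattice()].
#' @param flags per-cell gene activity from [assign_domains()].
#' @param config a [sim_config()].
#' @param genotype `"WT"` or `"KO"`.
#' @param gene which gene's transcription to simulate (a column of `flags`).
#' @param seed stream seed; defaults to `config$seed`. Pass distinct values
#'   for distinct embryos.
#' @return A `ground_truth` object: list with
#'   \describe{
#'     \item{cells}{data.frame `(label, genotype, true_mrna, true_ts)`.}
#'     \item{alleles}{data.frame `(label, allele, active, nascent)`.}
#'   }
#' @export
simulate_transcription <- function(cellmap, flags, config,
                                   genotype = c("WT", "KO"),
                                   gene = "rho", seed = config$seed) {
  validate_sim_config(config)
  genotype <- match.arg(genotype)
  if (config$t_end <= 0) stop("t_end must be positive")
  k_deg <- genotype_k_deg(config, genotype)
  ks <- config$k_on + config$k_off
  p_on <- if (ks > 0) config$k_on / ks else 0
  active_gene <- flags[[gene]][match(cellmap$cells$label, flags$label)]

  n <- nrow(cellmap$cells)
  counts <- integer(n)
  ts <- integer(n)
  allele_rows <- vector("list", n)
  geno_tag <- if (genotype == "KO") 2L else 1L
  lam_nasc <- max(config$nascent_mean - 1, 0)
  for (i in seq_len(n)) {
    lab <- cellmap$cells$label[i]
    res <- with_seed(derive_seed(seed, 7919L, lab, geno_tag), {
      if (isTRUE(active_gene[i])) {
        st <- telegraph_alleles(config$n_alleles, config$k_on, config$k_off,
                                config$k_tx, k_deg, config$t_end, p_on)
        nasc <- ifelse(st[, 2] == 1L, 1L + rpois(nrow(st), lam_nasc), 0L)
        list(m = st[, 1], on = st[, 2], nasc = nasc)
      } else {
        # leaky constitutive birth-death started at 0 is exactly Poisson
        lam <- config$leak_frac * config$k_tx
        mean_m <- if (k_deg > 0) lam / k_deg * (1 - exp(-k_deg * config$t_end))
                  else lam * config$t_end
        list(m = rpois(config$n_alleles, mean_m),
             on = integer(config$n_alleles),
             nasc = integer(config$n_alleles))
      }
    })
    counts[i] <- sum(res$m)
    ts[i] <- sum(res$on)
    allele_rows[[i]] <- data.frame(label = lab,
                                   allele = seq_along(res$m),
                                   active = res$on, nascent = res$nasc)
  }
  structure(list(
    cells = data.frame(label = cellmap$cells$label, genotype = genotype,
                       true_mrna = counts, true_ts = ts),
    alleles = do.call(rbind, allele_rows)
  ), class = "ground_truth")
}

#' Deterministic protein accumulation per cell
#'
#' Protein follows a linear birth-death model sourced by the genotype's
#' stationary mean mRNA: synthesis starts at the genotype's onset time
#' (`protein_onset_wt` / `protein_onset_ko`) in rho-active cells and is zero
#' before it, giving
#' \deqn{P(t) = \frac{k_{tr} \bar m}{k_{pdeg}} (1 - e^{-k_{pdeg}(t - t_{on})})}
#' for `t > t_on`. The KO onset precedes the WT onset by default, so at times
#' between the two onsets the KO carries protein while the WT does not — the
#' premature-protein contrast the protein experiment measures.
#'
#' @param cellmap a `cell_map`.
#' @param flags output of [assign_domains()].
#' @param config a [sim_config()].
#' @param genotype `"WT"` or `"KO"`.
#' @param t_query time in minutes (`>= 0`).
#' @return data.frame `(label, protein)` in arbitrary units.
#' @export
simulate_protein <- function(cellmap, flags, config,
                             genotype = c("WT", "KO"), t_query) {
  validate_sim_config(config)
  genotype <- match.arg(genotype)
  if (!is.finite(t_query) || t_query < 0) stop("t_query must be >= 0")
  onset <- if (genotype == "KO") config$protein_onset_ko else config$protein_onset_wt
  active <- flags$rho[match(cellmap$cells$label, flags$label)]
  mbar <- telegraph_mean(config, genotype)
  dt <- t_query - onset
  level <- if (dt <= 0) 0 else if (config$k_pdeg > 0)
    config$k_translate * mbar / config$k_pdeg * (1 - exp(-config$k_pdeg * dt))
  else config$k_translate * mbar * dt
  data.frame(label = cellmap$cells$label,
             protein = ifelse(active, level, 0))
}
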