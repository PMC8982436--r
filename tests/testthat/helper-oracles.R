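# Shared fixtures and independent oracles for the test suite.
options(embryoquant.quiet = TRUE)

# small fast configs ---------------------------------------------------------

# counts-only work: tiny pixel pitch keeps rasters small
counts_config <- function(...) {
  sim_config(n_cols = 25, n_rows = 24, cell_pitch_px = 8, jitter = 0.15,
             domain_spec = list(rho = c(0, 1), mir9a = c(0, 1)), ...)
}

# independent closed-form telegraph moments (written from the model, not
# calling the package's own helpers)
oracle_telegraph_mean <- function(cfg, k_deg) {
  cfg$n_alleles * (cfg$k_on / (cfg$k_on + cfg$k_off)) * cfg$k_tx / k_deg
}
oracle_telegraph_var <- function(cfg, k_deg) {
  ks <- cfg$k_on + cfg$k_off
  m <- oracle_telegraph_mean(cfg, k_deg)
  m * (1 + cfg$k_tx * cfg$k_off / (ks * (ks + k_deg)))
}

# standard error of a sample variance from sample central moments
se_of_variance <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  sqrt((m4 - m2^2 * (n - 3) / (n - 1)) / n)
}

# brute-force dispersion oracle ----------------------------------------------
# recomputes every cluster statistic directly from the raw table and the
# adjacency lists, with explicit formulas
brute_dispersion <- function(cells, graph, include_focal = TRUE) {
  counts <- cells$mrna_count[match(graph$nodes, cells$label)]
  names(counts) <- as.character(graph$nodes)
  res <- list()
  for (f in graph$nodes) {
    if (graph$border[[as.character(f)]]) next
    mem <- graph$adj[[as.character(f)]]
    if (include_focal) mem <- c(f, mem)
    v <- as.numeric(counts[as.character(mem)])
    n <- length(v)
    if (n < 3) {
      res[[as.character(f)]] <- c(f, n, NA, NA, NA, NA); next
    }
    m <- sum(v) / n
    s2 <- sum((v - m)^2) / (n - 1)
    if (m == 0) res[[as.character(f)]] <- c(f, n, m, s2, NA, NA)
    else res[[as.character(f)]] <- c(f, n, m, s2, s2 / m, sqrt(s2) / m)
  }
  out <- do.call(rbind, res)
  colnames(out) <- c("label", "cluster_size", "cluster_mean", "cluster_var",
                     "fano", "cv")
  as.data.frame(out)
}

# naive seed-site scanner -----------------------------------------------------
# tests every UTR window against the pairing rules directly (independent of
# the package's pattern-precomputation route), then applies the same
# precedence: 8mer > 7mer-m8 > 7mer-A1, 7mers inside a reported 8mer window
# suppressed.
naive_scan <- function(utr, mirna) {
  comp <- c(A = "U", C = "G", G = "C", U = "A", N = "?")
  u <- strsplit(chartr("Tt", "UU", toupper(utr)), "")[[1]]
  m <- strsplit(chartr("Tt", "UU", toupper(mirna)), "")[[1]]
  L <- length(u)
  is8 <- function(p) { # p 1-based start; window p..p+7
    if (p + 7 > L) return(FALSE)
    for (k in 0:6) if (u[p + k] != comp[[m[8 - k]]]) return(FALSE)
    u[p + 7] == "A"
  }
  is7m8 <- function(p) {
    if (p + 6 > L) return(FALSE)
    for (k in 0:6) if (u[p + k] != comp[[m[8 - k]]]) return(FALSE)
    TRUE
  }
  is7a1 <- function(p) {
    if (p + 6 > L) return(FALSE)
    for (k in 0:5) if (u[p + k] != comp[[m[7 - k]]]) return(FALSE)
    u[p + 6] == "A"
  }
  s8 <- Filter(is8, seq_len(L)); s8 <- as.integer(s8)
  inside8 <- function(p) any(p >= s8 & p + 6 <= s8 + 7)
  s7m8 <- as.integer(Filter(function(p) is7m8(p) &&
                              (!length(s8) || !inside8(p)), seq_len(L)))
  s7a1 <- as.integer(Filter(function(p) is7a1(p) &&
                              (!length(s8) || !inside8(p)), seq_len(L)))
  s7a1 <- setdiff(s7a1, s7m8)
  out <- rbind(
    if (length(s8)) data.frame(position = s8 - 1L, site_type = "8mer"),
    if (length(s7m8)) data.frame(position = s7m8 - 1L, site_type = "7mer-m8"),
    if (length(s7a1)) data.frame(position = s7a1 - 1L, site_type = "7mer-A1"))
  if (is.null(out))
    return(data.frame(position = integer(0), site_type = character(0)))
  out[order(out$position), , drop = FALSE]
}

random_rna <- function(n, with_n = FALSE) {
  ab <- c("A", "C", "G", "U", if (with_n) "N")
  paste(sample(ab, n, replace = TRUE), collapse = "")
}

# handcrafted single-cell ground truth for rendering tests
manual_ground_truth <- function(label = 1L, n_mrna = 1L, ts_active = 0L,
                                nascent = integer(0)) {
  structure(list(
    cells = data.frame(label = label, genotype = "WT",
                       true_mrna = n_mrna, true_ts = ts_active),
    alleles = data.frame(label = rep(label, max(ts_active, length(nascent))),
                         allele = seq_len(max(ts_active, length(nascent))),
                         active = rep(1L, ts_active),
                         nascent = if (length(nascent)) nascent
                                   else rep(1L, ts_active))[
                           seq_len(ts_active), , drop = FALSE]
  ), class = "ground_truth")
}
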