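#' Canonical target-site patterns for a miRNA
#'
#' Derives the three canonical seed-site patterns a miRNA can form on a
#' 3'UTR, from the miRNA sequence given 5'->3':
#' \describe{
#'   \item{8mer}{reverse complement of miRNA nt 2-8, followed by A (the A
#'     opposite nt 1 is a sequence feature of the target, not a pairing).}
#'   \item{7mer-m8}{reverse complement of nt 2-8.}
#'   \item{7mer-A1}{reverse complement of nt 2-7, followed by A.}
#' }
#' Only nt 1-8 of the miRNA enter the definitions; the 3' end is ignored.
#'
#' @param mirna_seq miRNA sequence, 5'->3', RNA or DNA alphabet (at least
#'   8 nt).
#' @param alphabet output alphabet for the patterns, `"RNA"` (default) or
#'   `"DNA"`.
#' @return named character vector with elements `8mer`, `7mer-m8`,
#'   `7mer-A1`.
#' @examples
#' seed_match_patterns("UACGUACGCCCC")
#' @export
seed_match_patterns <- function(mirna_seq, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  s <- canonicalize_rna(mirna_seq, allow_n = FALSE)
  if (nchar(s) < 8) stop("miRNA must be at least 8 nt")
  rc <- function(x) chartr("ACGU", "UGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  p <- c("8mer" = paste0(rc(substr(s, 2, 8)), "A"),
         "7mer-m8" = rc(substr(s, 2, 8)),
         "7mer-A1" = paste0(rc(substr(s, 2, 7)), "A"))
  if (alphabet == "DNA") p[] <- chartr("U", "T", p)
  p
}

# internal: uppercase, DNA->RNA, validate alphabet
canonicalize_rna <- function(seq, allow_n = TRUE) {
  s <- chartr("tu", "TU", toupper(as.character(seq)))
  s <- chartr("T", "U", s)
  ok <- if (allow_n) "^[ACGUN]*$" else "^[ACGU]*$"
  if (!grepl(ok, s)) stop("invalid characters in sequence")
  s
}

#' Scan a 3'UTR for canonical miRNA seed sites
#'
#' Slides the three canonical patterns of the miRNA along the UTR. At each
#' position at most one site is reported, with precedence
#' 8mer > 7mer-m8 > 7mer-A1: a 7mer whose window lies inside a reported
#' 8mer window is suppressed (it is the same physical site). `N` bases never
#' match. Positions are 0-based indices of the site's first nucleotide on
#' the UTR by default (the UTR start is position 0); 1-based output is
#' available via `one_based`.
#'
#' @param utr_seq UTR sequence (RNA or DNA; `N` allowed).
#' @param mirna_seq miRNA sequence, 5'->3'.
#' @param utr_id,mirna_id identifiers carried into the output.
#' @param one_based report 1-based positions instead of 0-based.
#' @param alias_7mer use the aliases `7_m8` / `7_A1` for the 7mer types.
#' @return data.frame `(utr_id, mirna_id, position, site_type,
#'   site_sequence)`, sorted by position; zero rows when the UTR is shorter
#'   than 7 nt or carries no site.
#' @export
scan_utr <- function(utr_seq, mirna_seq, utr_id = "utr", mirna_id = "mirna",
                     one_based = FALSE, alias_7mer = FALSE) {
  utr <- canonicalize_rna(utr_seq, allow_n = TRUE)
  pats <- seed_match_patterns(mirna_seq)
  empty <- data.frame(utr_id = character(0), mirna_id = character(0),
                      position = integer(0), site_type = character(0),
                      site_sequence = character(0))
  if (nchar(utr) < 7) return(empty)

  find_all <- function(pattern) {
    hits <- gregexpr(pattern, utr, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)  # 1-based starts
  }
  s8 <- find_all(pats["8mer"])
  s7m8 <- find_all(pats["7mer-m8"])
  s7a1 <- find_all(pats["7mer-A1"])

  # suppress 7mers contained in a reported 8mer window [s, s+7]
  contained <- function(p, width) {
    vapply(p, function(q) any(q >= s8 & (q + width - 1) <= (s8 + 7)),
           logical(1))
  }
  if (length(s8)) {
    if (length(s7m8)) s7m8 <- s7m8[!contained(s7m8, 7)]
    if (length(s7a1)) s7a1 <- s7a1[!contained(s7a1, 7)]
  }
  # one hit per start position: m8 beats A1
  s7a1 <- setdiff(s7a1, s7m8)

  tn <- if (alias_7mer) c("8mer", "7_m8", "7_A1")
        else c("8mer", "7mer-m8", "7mer-A1")
  out <- rbind(
    data.frame(position = s8, site_type = rep(tn[1], length(s8)),
               width = rep(8L, length(s8))),
    data.frame(position = s7m8, site_type = rep(tn[2], length(s7m8)),
               width = rep(7L, length(s7m8))),
    data.frame(position = s7a1, site_type = rep(tn[3], length(s7a1)),
               width = rep(7L, length(s7a1))))
  if (nrow(out) == 0) return(empty)
  out <- out[order(out$position), , drop = FALSE]
  data.frame(utr_id = utr_id, mirna_id = mirna_id,
             position = out$position - if (one_based) 0L else 1L,
             site_type = out$site_type,
             site_sequence = substring(utr, out$position,
                                       out$position + out$width - 1L),
             row.names = NULL)
}

#' Scan all miRNA x UTR pairs from FASTA files
#'
#' Reads UTRs and miRNAs from FASTA, scans every pair with [scan_utr()],
#' and returns (optionally writes as TSV) the combined hit table.
#'
#' @param utr_fasta,mirna_fasta FASTA file paths. Empty files or duplicated
#'   ids are errors.
#' @param out optional TSV output path.
#' @param ... passed to [scan_utr()] (`one_based`, `alias_7mer`).
#' @return data.frame of hits across all pairs (zero rows when no pair has
#'   a site).
#' @export
batch_scan <- function(utr_fasta, mirna_fasta, out = NULL, ...) {
  utrs <- Biostrings::readBStringSet(utr_fasta)
  mirnas <- Biostrings::readBStringSet(mirna_fasta)
  if (length(utrs) == 0 || length(mirnas) == 0)
    stop("empty FASTA input")
  uid <- sub("\\s.*$", "", names(utrs))
  mid <- sub("\\s.*$", "", names(mirnas))
  if (anyDuplicated(uid) || anyDuplicated(mid))
    stop("duplicate sequence ids in FASTA input")
  res <- list()
  for (i in seq_along(utrs)) for (j in seq_along(mirnas)) {
    res[[length(res) + 1L]] <- scan_utr(as.character(utrs[[i]]),
                                        as.character(mirnas[[j]]),
                                        utr_id = uid[i], mirna_id = mid[j],
                                        ...)
  }
  hits <- do.call(rbind, res)
  if (!is.null(out))
    utils::write.table(hits, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  hits
}
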