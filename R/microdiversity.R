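#' Per-site nucleotide frequency vectors
#'
#' Normalises A/C/G/T read counts to frequencies \eqn{f_X = n_X / depth}.
#'
#' @param counts data.frame (or single row) with columns \code{nA},
#'   \code{nC}, \code{nG}, \code{nT}; or a numeric vector of length 4 in
#'   that order.
#' @return numeric matrix with columns \code{fA}, \code{fC}, \code{fG},
#'   \code{fT}, one row per site.
#' @export
#' @examples
#' site_frequencies(c(nA = 30, nC = 0, nG = 20, nT = 10))
site_frequencies <- function(counts) {
  if (is.numeric(counts) && is.null(dim(counts)))
    counts <- as.data.frame(as.list(stats::setNames(
      counts, c("nA", "nC", "nG", "nT")[seq_along(counts)])))
  m <- as.matrix(counts[, c("nA", "nC", "nG", "nT")])
  depth <- rowSums(m)
  if (any(depth == 0))
    stop("uncovered site(s): depth 0 at row(s) ",
         paste(which(depth == 0), collapse = ", "))
  f <- m / depth
  colnames(f) <- c("fA", "fC", "fG", "fT")
  f
}

#' Per-site nucleotide diversity
#'
#' \eqn{ND = 1 - (f_A^2 + f_C^2 + f_G^2 + f_T^2)}; ranges from 0
#' (monomorphic) to 0.75 (all four alleles equally frequent).
#'
#' @param f frequency matrix from \code{\link{site_frequencies}} (or a
#'   numeric vector of 4 frequencies).
#' @return numeric vector of per-site ND values.
#' @export
site_nd <- function(f) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
  1 - rowSums(f^2)
}

#' Call SNV sites for one MAG in one sample
#'
#' A site is a single-nucleotide variant when it is covered at the minimum
#' depth (default 5x) and carries at least two alleles, with the strongest
#' minor allele supported by both a minimum read count (default 2) and a
#' minimum frequency (default 5%).
#'
#' @param sites data.frame of site counts for one (MAG, sample):
#'   columns \code{position}, \code{nA}, \code{nC}, \code{nG}, \code{nT}.
#' @param min_depth minimum coverage depth (default 5).
#' @param min_alt_reads minimum reads supporting the top minor allele
#'   (default 2).
#' @param min_alt_freq minimum frequency of the top minor allele
#'   (default 0.05).
#' @return integer vector of SNV positions (0-based, as supplied).
#' @export
call_snv_sites <- function(sites, min_depth = gv_config()$min_depth,
                           min_alt_reads = gv_config()$min_alt_reads,
                           min_alt_freq = gv_config()$min_alt_freq) {
  m <- as.matrix(sites[, c("nA", "nC", "nG", "nT")])
  if (nrow(m) == 0L) return(sites$position[0])
  depth <- rowSums(m)
  sorted <- t(apply(m, 1L, sort, decreasing = TRUE))
  minor <- sorted[, 2L]
  is_snv <- depth >= min_depth &
    minor >= min_alt_reads &
    minor / pmax(depth, 1L) >= min_alt_freq
  sites$position[is_snv]
}

#' Genome-wide nucleotide diversity
#'
#' The mean of per-site ND over the genome's SNV sites. With no SNV site
#' the value is reported as 0 and flagged.
#'
#' @param site_nds numeric vector of per-site ND values at SNV sites.
#' @return numeric scalar with attribute \code{"no_snv"} (logical).
#' @export
genome_nd <- function(site_nds) {
  if (length(site_nds) == 0L)
    return(structure(0, no_snv = TRUE))
  structure(mean(site_nds), no_snv = FALSE)
}

#' SNV density per megabase
#'
#' @param n_sites number of SNV sites.
#' @param genome_len genome length in bp (> 0).
#' @return SNV sites per Mb.
#' @export
snv_per_mb <- function(n_sites, genome_len) {
  if (any(genome_len <= 0)) stop("genome length must be positive")
  n_sites / (genome_len / 1e6)
}

#' Between-sample allele distance at one site
#'
#' The probability that two reads drawn from samples a and b differ:
#' \eqn{\pi(a,b) = \sum_X a_X (1 - b_X)}. Algebraically symmetric in the
#' two samples, and \eqn{\pi(a,a)} equals the site ND.
#'
#' @param a,b frequency vectors (length 4) or aligned frequency matrices.
#' @return numeric vector of per-site distances.
#' @export
pi_between <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  stopifnot(all(dim(a) == dim(b)))
  rowSums(a * (1 - b))
}

#' Microdiversity profile of one MAG in one sample
#'
#' Calls SNV sites and summarises genome-wide ND and SNV density.
#'
#' @param sites site-count data.frame for one (MAG, sample).
#' @param genome_len genome length in bp.
#' @param config configuration list (SNV thresholds).
#' @return data.frame row with \code{n_snv_sites}, \code{genome_nd},
#'   \code{snv_per_mb}, \code{no_snv}.
#' @export
microdiv_profile <- function(sites, genome_len, config = gv_config()) {
  snv <- call_snv_sites(sites, config$min_depth, config$min_alt_reads,
                        config$min_alt_freq)
  sub <- sites[sites$position %in% snv, , drop = FALSE]
  nd <- if (nrow(sub)) site_nd(site_frequencies(sub)) else numeric()
  g <- genome_nd(nd)
  data.frame(n_snv_sites = length(snv), genome_nd = as.numeric(g),
             snv_per_mb = snv_per_mb(length(snv), genome_len),
             no_snv = isTRUE(attr(g, "no_snv")))
}

# Align two per-site count tables on position and return the shared-site
# universe for the fixation index.
shared_snv_sites <- function(sites_a, sites_b, min_depth, min_alt_reads,
                             min_alt_freq, rule) {
  rule <- match.arg(rule, c("union", "both", "cocovered"))
  pos <- intersect(sites_a$position, sites_b$position)
  a <- sites_a[match(pos, sites_a$position), , drop = FALSE]
  b <- sites_b[match(pos, sites_b$position), , drop = FALSE]
  da <- rowSums(a[, c("nA", "nC", "nG", "nT")])
  db <- rowSums(b[, c("nA", "nC", "nG", "nT")])
  covered <- da >= min_depth & db >= min_depth
  if (rule == "cocovered") {
    # any co-covered site that is polymorphic in the pooled counts
    pooled <- a[, c("nA", "nC", "nG", "nT")] + b[, c("nA", "nC", "nG", "nT")]
    poly <- apply(pooled, 1L, function(x) sum(x > 0) >= 2L)
    return(pos[covered & poly])
  }
  snv_a <- call_snv_sites(a, min_depth, min_alt_reads, min_alt_freq)
  snv_b <- call_snv_sites(b, min_depth, min_alt_reads, min_alt_freq)
  sel <- if (rule == "union") union(snv_a, snv_b)
         else intersect(snv_a, snv_b)
  intersect(pos[covered], sel)
}

#' Fixation index between two samples for one MAG
#'
#' Genome-wide population differentiation:
#' \eqn{f_{st} = 1 - \frac{(\bar\pi(a,a) + \bar\pi(b,b))/2}{\bar\pi(a,b)}}
#' where each \eqn{\bar\pi} is the mean per-site allele distance over the
#' shared SNV-site universe (by default: sites called SNV in at least one
#' of the two samples and covered at the minimum depth in both). The
#' microdiversity similarity is \code{1 - fst}. When the between-sample
#' distance is zero the pair is monomorphic and identical; fst is defined
#' as 0 and flagged.
#'
#' @param sites_a,sites_b site-count data.frames for the same MAG in two
#'   samples (columns \code{position}, \code{nA}..\code{nT}).
#' @param config configuration list (\code{min_depth},
#'   \code{min_alt_reads}, \code{min_alt_freq}, \code{shared_sites}).
#' @return data.frame row: \code{n_shared_sites}, \code{mean_pi_aa},
#'   \code{mean_pi_bb}, \code{mean_pi_ab}, \code{fst}, \code{similarity},
#'   \code{comparable}, \code{monomorphic}.
#' @export
fst_pair <- function(sites_a, sites_b, config = gv_config()) {
  shared <- shared_snv_sites(sites_a, sites_b, config$min_depth,
                             config$min_alt_reads, config$min_alt_freq,
                             config$shared_sites)
  if (length(shared) == 0L)
    return(data.frame(n_shared_sites = 0L, mean_pi_aa = NA_real_,
                      mean_pi_bb = NA_real_, mean_pi_ab = NA_real_,
                      fst = NA_real_, similarity = NA_real_,
                      comparable = FALSE, monomorphic = NA))
  a <- sites_a[match(shared, sites_a$position), , drop = FALSE]
  b <- sites_b[match(shared, sites_b$position), , drop = FALSE]
  fa <- site_frequencies(a)
  fb <- site_frequencies(b)
  pi_aa <- mean(pi_between(fa, fa))
  pi_bb <- mean(pi_between(fb, fb))
  pi_ab <- mean((pi_between(fa, fb) + pi_between(fb, fa)) / 2)
  if (pi_ab == 0) {
    fst <- 0
    mono <- TRUE
  } else {
    fst <- 1 - ((pi_aa + pi_bb) / 2) / pi_ab
    mono <- FALSE
  }
  data.frame(n_shared_sites = length(shared), mean_pi_aa = pi_aa,
             mean_pi_bb = pi_bb, mean_pi_ab = pi_ab, fst = fst,
             similarity = 1 - fst, comparable = TRUE, monomorphic = mono)
}

#' Microdiversity similarity time course of one MAG
#'
#' Computes 1 - fst for every pair of samples in which the MAG passes the
#' abundance filter, together with the day separation of the pair.
#' Non-comparable pairs (no shared SNV sites) are logged and excluded.
#'
#' @param site_counts site-count data.frame for one MAG across samples
#'   (columns \code{sample_id}, \code{position}, \code{nA}..\code{nT}).
#' @param sample_dates named \code{Date} vector over samples.
#' @param abundant_samples character vector of samples in which the MAG is
#'   abundant (the presence/abundance rule applied upstream); defaults to
#'   all samples present in \code{site_counts}.
#' @param config configuration list.
#' @return data.frame with one row per comparable pair: \code{sample_a},
#'   \code{sample_b}, \code{interval_days}, \code{fst}, \code{similarity};
#'   attribute \code{"skipped"} lists non-comparable pairs.
#' @export
microdiv_timecourse <- function(site_counts, sample_dates,
                                abundant_samples = NULL,
                                config = gv_config()) {
  samples <- sort(unique(site_counts$sample_id))
  if (!is.null(abundant_samples))
    samples <- intersect(samples, abundant_samples)
  if (length(samples) < 2L)
    return(structure(data.frame(sample_a = character(),
                                sample_b = character(),
                                interval_days = numeric(),
                                fst = numeric(), similarity = numeric(),
                                stringsAsFactors = FALSE),
                     skipped = character()))
  idx <- utils::combn(length(samples), 2L)
  rows <- list()
  skipped <- character()
  for (cc in seq_len(ncol(idx))) {
    sa <- samples[idx[1L, cc]]; sb <- samples[idx[2L, cc]]
    res <- fst_pair(site_counts[site_counts$sample_id == sa, , drop = FALSE],
                    site_counts[site_counts$sample_id == sb, , drop = FALSE],
                    config)
    if (!res$comparable) {
      skipped <- c(skipped, paste(sa, sb, sep = ":"))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_a = sa, sample_b = sb,
      interval_days = abs(as.numeric(sample_dates[[sb]] -
                                       sample_dates[[sa]])),
      fst = res$fst, similarity = res$similarity,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(sample_a = character(), sample_b = character(),
                         interval_days = numeric(), fst = numeric(),
                         similarity = numeric(), stringsAsFactors = FALSE)
  structure(out, skipped = skipped)
}
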