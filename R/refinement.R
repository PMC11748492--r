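#' Giant-virus characteristic score of one contig
#'
#' A contig scores one point for every taxonomic classifier (out of at most
#' three) that assigns it to the target giant-virus lineage, plus one point
#' if it carries at least one hit against the marker HMM collection, giving
#' an integer in [0, 4].
#'
#' @param verdicts character vector of verdicts for one contig (one entry
#'   per tool; values \code{target_lineage}, \code{other} or \code{none}).
#' @param hmm_hit logical, does the contig have any marker HMM hit?
#' @return integer score in [0, 4].
#' @export
#' @examples
#' characteristic_score(c("target_lineage", "other", "target_lineage"), TRUE)
characteristic_score <- function(verdicts, hmm_hit) {
  if (length(verdicts) > 3L)
    stop("configuration error: more than three classifier verdicts for one",
         " contig")
  bad <- setdiff(verdicts, c("target_lineage", "other", "none"))
  if (length(bad))
    stop("unknown verdict value(s): ", paste(bad, collapse = ", "))
  as.integer(sum(verdicts == "target_lineage") + isTRUE(hmm_hit))
}

#' Characteristic scores for a set of contigs
#'
#' Table-level wrapper over \code{\link{characteristic_score}}.
#'
#' @param contig_ids character vector of contigs to score (contigs without
#'   any verdict or hit score 0).
#' @param verdicts verdict table (\code{contig_id}, \code{tool_name},
#'   \code{verdict}).
#' @param hmm_hit_contigs character vector of contig ids with at least one
#'   marker HMM hit.
#' @return named integer vector of scores, one per \code{contig_ids}.
#' @export
characteristic_scores <- function(contig_ids, verdicts, hmm_hit_contigs) {
  tools <- unique(verdicts$tool_name)
  if (length(tools) > 3L)
    stop("configuration error: ", length(tools),
         " classifier tools configured (at most 3 allowed)")
  n_target <- integer(length(contig_ids))
  names(n_target) <- contig_ids
  if (nrow(verdicts)) {
    hit <- verdicts[verdicts$verdict == "target_lineage" &
                      verdicts$contig_id %in% contig_ids, , drop = FALSE]
    tab <- table(factor(hit$contig_id, levels = contig_ids))
    n_target <- as.integer(tab)
    names(n_target) <- contig_ids
  }
  score <- n_target + as.integer(contig_ids %in% hmm_hit_contigs)
  names(score) <- contig_ids
  score
}

#' Remove bins without giant-virus features
#'
#' A bin is discarded when it lacks every one of the five NCLDV hallmark
#' genes (MCP, PolB, TFIIB, TopoII, A32) \emph{and} strictly more than 90%
#' of its contigs carry a characteristic score of 0. Both conditions are
#' logged per bin.
#'
#' @param bins list of \code{\link{gv_bin}} objects with populated
#'   \code{char_score} and marker hits.
#' @param config configuration list from \code{\link{gv_config}}.
#' @return list with components \code{kept} and \code{removed} (lists of
#'   bins) and \code{audit} (one row per bin with the evaluated conditions).
#' @export
remove_non_gv_bins <- function(bins, config = gv_config()) {
  stopifnot(all(vapply(bins, inherits, logical(1), "gv_bin")))
  audit <- lapply(bins, function(b) {
    if (anyNA(b$contigs$char_score))
      stop("bin '", b$bin_id, "' has unscored contigs")
    hall <- hallmark_present(b, config$hallmark_genes)
    f0 <- mean(b$contigs$char_score == 0L)
    removed <- length(hall) == 0L && f0 > config$score0_bin_fraction
    data.frame(bin_id = b$bin_id, n_hallmarks = length(hall),
               frac_score0 = f0, removed = removed,
               reason = if (removed) "no_hallmark_and_score0_majority"
                        else "kept",
               stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, audit)
  list(kept = bins[!audit$removed], removed = bins[audit$removed],
       audit = audit)
}

# Sentinel returned when a QC step empties a bin; carries the audit trail.
dropped_bin <- function(audit)
  structure(list(), class = "gv_dropped", audit = audit)

#' Was a bin dropped by a refinement step?
#'
#' @param x result of a refinement operation.
#' @return TRUE when the step emptied the bin (the audit trail is in
#'   \code{attr(x, "audit")}).
#' @export
is_dropped <- function(x) inherits(x, "gv_dropped")

# Rebuild a bin from a subset of its contigs (keeps tetra/markers aligned).
subset_bin <- function(bin, keep_ids) {
  contigs <- bin$contigs[bin$contigs$contig_id %in% keep_ids, , drop = FALSE]
  rownames(contigs) <- NULL
  tetra <- if (!is.null(bin$tetra))
    bin$tetra[contigs$contig_id, , drop = FALSE] else NULL
  markers <- if (!is.null(bin$markers))
    bin$markers[bin$markers$contig_id %in% keep_ids, , drop = FALSE] else NULL
  gv_bin(bin$bin_id, contigs, tetra = tetra, markers = markers)
}

#' Remove score-0 contigs from a bin
#'
#' First-stage decontamination: contigs whose characteristic score is 0 are
#' treated as misbinned cellular sequence and removed; genome size is
#' recomputed from the survivors.
#'
#' @param bin a scored \code{\link{gv_bin}}.
#' @return the stripped bin, or \code{NULL} when no contig survives (the
#'   empty-bin signal); either way attribute \code{"audit"} lists removals.
#' @export
strip_zero_contigs <- function(bin) {
  stopifnot(inherits(bin, "gv_bin"))
  if (anyNA(bin$contigs$char_score))
    stop("bin '", bin$bin_id, "' has unscored contigs")
  drop <- bin$contigs$contig_id[bin$contigs$char_score == 0L]
  audit <- if (length(drop))
    gv_audit(drop, "contig_removed", "char_score_0") else empty_audit()
  if (length(drop) == nrow(bin$contigs))
    return(dropped_bin(rbind(audit,
                             gv_audit(bin$bin_id, "bin_dropped",
                                      "all_contigs_score_0"))))
  out <- subset_bin(bin, setdiff(bin$contigs$contig_id, drop))
  attr(out, "audit") <- audit
  out
}

#' Outlier-based contig decontamination
#'
#' Second-stage decontamination. A contig is an outlier when its coverage
#' falls outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR] (quartiles by linear
#' interpolation over the bin's contig coverages) or when its score on the
#' first principal component of the bin's column-standardised
#' tetranucleotide matrix lies beyond 2.5 standard deviations. Outliers are
#' removed only when their characteristic score is exactly 1; stronger
#' evidence of viral origin (score >= 2) protects a contig. Bins with fewer
#' than four contigs pass through unchanged with a too-small flag, as
#' quartiles are not meaningful.
#'
#' @param bin a scored \code{\link{gv_bin}} with tetra profiles attached.
#' @param config configuration list.
#' @return the decontaminated bin with attribute \code{"audit"}.
#' @export
outlier_decontaminate <- function(bin, config = gv_config()) {
  stopifnot(inherits(bin, "gv_bin"))
  if (nrow(bin$contigs) < 4L) {
    attr(bin, "audit") <- gv_audit(bin$bin_id, "bin_passed",
                                   "too_small_for_outlier_test")
    return(bin)
  }
  cov <- bin$contigs$coverage
  q <- stats::quantile(cov, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  cov_out <- cov < q[1L] - config$iqr_factor * iqr |
             cov > q[2L] + config$iqr_factor * iqr
  tetra_out <- rep(FALSE, nrow(bin$contigs))
  if (!is.null(bin$tetra)) {
    m <- bin$tetra
    keep_col <- apply(m, 2L, stats::sd) > 0
    if (any(keep_col)) {
      pc <- stats::prcomp(m[, keep_col, drop = FALSE], center = TRUE,
                          scale. = TRUE)
      z <- as.numeric(scale(pc$x[, 1L]))
      tetra_out <- abs(z) > config$pc1_sd_limit
    }
  }
  drop <- (cov_out | tetra_out) & bin$contigs$char_score == 1L
  audit <- if (any(drop))
    gv_audit(bin$contigs$contig_id[drop], "contig_removed",
             ifelse(cov_out[drop] & tetra_out[drop], "coverage_and_tetra_outlier",
                    ifelse(cov_out[drop], "coverage_outlier",
                           "tetra_outlier"))) else empty_audit()
  if (all(drop))
    return(dropped_bin(rbind(audit, gv_audit(bin$bin_id, "bin_dropped",
                                             "all_contigs_outliers"))))
  out <- subset_bin(bin, bin$contigs$contig_id[!drop])
  attr(out, "audit") <- audit
  out
}

#' Flag a bin as a potential chimera
#'
#' A bin is a chimera suspect when its coverage coefficient of variation
#' (sd/mean over member contig coverages) exceeds 1 \emph{and} at least one
#' designated single-copy marker gene is present in two or more copies
#' across the bin.
#'
#' @param bin a \code{\link{gv_bin}} with coverages and marker hits.
#' @param config configuration list (\code{single_copy_markers},
#'   \code{cov_cv_limit}).
#' @return logical scalar.
#' @export
detect_chimera <- function(bin, config = gv_config()) {
  stopifnot(inherits(bin, "gv_bin"))
  cv <- cov_cv(bin)
  if (cv <= config$cov_cv_limit) return(FALSE)
  if (is.null(bin$markers)) return(FALSE)
  sc <- bin$markers[bin$markers$marker_id %in% config$single_copy_markers, ,
                    drop = FALSE]
  if (nrow(sc) == 0L) return(FALSE)
  any(tapply(sc$copy_count, sc$marker_id, sum) >= 2L)
}

# Evaluate the four split-acceptance criteria for one candidate cluster.
evaluate_split_cluster <- function(bin, config) {
  fails <- character()
  if (genome_size(bin) <= config$min_cluster_len)
    fails <- c(fails, "min-length")
  sc <- if (!is.null(bin$markers))
    bin$markers[bin$markers$marker_id %in% config$single_copy_markers, ,
                drop = FALSE]
  else bin$markers
  if (is.null(sc) || nrow(sc) == 0L)
    fails <- c(fails, "no-single-copy-marker")
  if (mean(bin$contigs$char_score == 4L) <= config$score4_fraction)
    fails <- c(fails, "score-fraction")
  sp <- bin$contigs$species[!is.na(bin$contigs$species)]
  if (length(sp) == 0L ||
      max(table(sp)) / length(sp) < config$species_consistency)
    fails <- c(fails, "taxonomy-inconsistent")
  fails
}

#' Split a chimeric bin into two genomes
#'
#' Contigs are clustered on standardised coverage-plus-tetranucleotide
#' features (Ward linkage on Euclidean distance, cut at k = 2). The split is
#' accepted only when \emph{both} clusters satisfy all four criteria:
#' total length > 40 kb, presence of at least one single-copy marker gene,
#' strictly more than 50% of contigs scoring 4, and a consistent
#' species-level taxonomy (>= 80% of classified contigs sharing one label).
#' Otherwise the bin is emitted unsplit and flagged, with the failed
#' criteria as reason codes.
#'
#' @param bin a chimera-flagged \code{\link{gv_bin}} with tetra profiles,
#'   scores, species labels and marker hits.
#' @param config configuration list.
#' @return a refinement report: list with \code{bin_id}, \code{action}
#'   (\code{"split"} or \code{"flagged_chimera_unsplit"}), \code{clusters}
#'   (list of two \code{gv_bin}s named \code{<bin_id>.1/.2} when split),
#'   \code{assignment} (named integer cluster index per contig) and
#'   \code{reasons} (failed criteria per cluster when unsplit).
#' @export
split_chimera <- function(bin, config = gv_config()) {
  stopifnot(inherits(bin, "gv_bin"))
  if (nrow(bin$contigs) < 2L)
    stop("cannot split bin '", bin$bin_id, "': fewer than 2 contigs")
  if (is.null(bin$tetra))
    stop("chimera splitting requires tetranucleotide profiles")
  feat <- cbind(coverage = bin$contigs$coverage, bin$tetra)
  keep_col <- apply(feat, 2L, stats::sd) > 0
  feat <- scale(feat[, keep_col, drop = FALSE])
  hc <- stats::hclust(stats::dist(feat), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2L)
  names(cl) <- bin$contigs$contig_id
  parts <- lapply(1:2, function(k) {
    sub <- subset_bin(bin, names(cl)[cl == k])
    sub$bin_id <- paste0(bin$bin_id, ".", k)
    sub
  })
  fails <- lapply(parts, evaluate_split_cluster, config = config)
  if (all(lengths(fails) == 0L)) {
    list(bin_id = bin$bin_id, action = "split", clusters = parts,
         assignment = cl, reasons = NULL)
  } else {
    list(bin_id = bin$bin_id, action = "flagged_chimera_unsplit",
         clusters = NULL, assignment = cl,
         reasons = stats::setNames(fails, c("cluster1", "cluster2")))
  }
}

#' Run the full refinement cascade
#'
#' Applies, in order: removal of bins without giant-virus features,
#' score-0 contig stripping, coverage/composition outlier decontamination,
#' and chimera detection with conditional splitting. Every input contig is
#' accounted for exactly once across kept bins and the audit trail.
#'
#' @param bins list of scored \code{\link{gv_bin}} objects.
#' @param config configuration list.
#' @return list with \code{bins} (refined \code{gv_bin}s, split products
#'   included), \code{report} (per-bin action data.frame) and \code{audit}
#'   (per-contig removal log with reason codes).
#' @export
refine_bins <- function(bins, config = gv_config()) {
  audit <- empty_audit()
  report <- list()
  step1 <- remove_non_gv_bins(bins, config)
  for (b in step1$removed) {
    audit <- rbind(audit, gv_audit(b$contigs$contig_id, "contig_removed",
                                   "bin_removed_non_gv"))
    report[[b$bin_id]] <- data.frame(bin_id = b$bin_id,
                                     action = "removed_bin",
                                     stringsAsFactors = FALSE)
  }
  out <- list()
  for (b in step1$kept) {
    n_in <- nrow(b$contigs)
    b2 <- strip_zero_contigs(b)
    audit <- rbind(audit, attr(b2, "audit"))
    if (is_dropped(b2)) {
      report[[b$bin_id]] <- data.frame(bin_id = b$bin_id,
                                       action = "removed_bin",
                                       stringsAsFactors = FALSE)
      next
    }
    b3 <- outlier_decontaminate(b2, config)
    aud3 <- attr(b3, "audit")
    audit <- rbind(audit, aud3[aud3$action == "contig_removed", ,
                               drop = FALSE])
    if (is_dropped(b3)) {
      report[[b$bin_id]] <- data.frame(bin_id = b$bin_id,
                                       action = "removed_bin",
                                       stringsAsFactors = FALSE)
      next
    }
    action <- if (nrow(b3$contigs) < n_in) "contigs_removed" else "kept"
    if (mean(b3$contigs$coverage) > 0 && detect_chimera(b3, config)) {
      sp <- split_chimera(b3, config)
      if (sp$action == "split") {
        out <- c(out, sp$clusters)
        report[[b$bin_id]] <- data.frame(bin_id = b$bin_id,
                                         action = "split",
                                         stringsAsFactors = FALSE)
        next
      }
      action <- "flagged_chimera_unsplit"
    }
    out <- c(out, list(b3))
    report[[b$bin_id]] <- data.frame(bin_id = b$bin_id, action = action,
                                     stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  list(bins = out, report = report, audit = audit)
}
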