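#' Default marker weight profile
#'
#' The density index sums per-marker weights that reflect how conserved each
#' of the 20 NCVOG marker genes is across giant-virus families. The
#' conservation-derived weights are dataset-specific; the shipped default is
#' a placeholder profile of 20 markers at weight 1.0 (the five hallmark
#' genes plus fifteen generic NCVOG slots), intended to be replaced by a
#' user-supplied table.
#'
#' @return data.frame with columns \code{marker_id}, \code{weight}.
#' @export
default_marker_weights <- function() {
  data.frame(
    marker_id = c("MCP", "PolB", "TFIIB", "TopoII", "A32",
                  sprintf("NCVOG_%02d", 6:20)),
    weight = 1.0,
    stringsAsFactors = FALSE)
}

#' Weighted core-gene density index
#'
#' Screens bins for giant-virus content by relating the summed conservation
#' weights of detected marker genes to genome size:
#' \deqn{\mathrm{index} = \frac{\sum_{k \in \mathrm{detected}} w_k}
#'   {\log_{10}(\mathrm{genome\ size}) - 4}}
#' Each marker counts once regardless of copy number. The denominator is
#' positive only above 10 kb, below which the index is undefined.
#'
#' @param detected_markers character vector of marker ids present in the
#'   bin (a set; duplicates are ignored).
#' @param weights weight table as from \code{\link{default_marker_weights}}.
#' @param genome_size genome size in bp (> 10000).
#' @return numeric density index.
#' @export
#' @examples
#' density_index(c("MCP", "PolB"), default_marker_weights(), 100000)
density_index <- function(detected_markers,
                          weights = default_marker_weights(),
                          genome_size) {
  stopifnot(is.numeric(genome_size), length(genome_size) == 1L)
  if (genome_size <= 10000)
    stop("density index undefined for genome size <= 10 kb (got ",
         genome_size, " bp)")
  if (any(weights$weight < 0 | weights$weight > 1))
    stop("marker weights must lie in [0, 1]")
  detected <- unique(as.character(detected_markers))
  unknown <- setdiff(detected, weights$marker_id)
  if (length(unknown))
    stop("detected marker(s) absent from the weight table: ",
         paste(unknown, collapse = ", "))
  wsum <- sum(weights$weight[weights$marker_id %in% detected])
  wsum / (log10(genome_size) - 4)
}

#' Screen bins for giant-virus candidates
#'
#' Applies the density index to every bin and calls candidates above the
#' screening threshold (strictly greater; the threshold sits in an empirical
#' gap between viral and cellular genomes, so boundary values are not
#' expected). Bins too small for the index (<= 10 kb) are reported as not
#' evaluable rather than dropped.
#'
#' @param bins data.frame with columns \code{bin_id}, \code{contig_id},
#'   \code{length} (bp per contig).
#' @param marker_hits aggregated hit table (\code{contig_id},
#'   \code{marker_id}, \code{copy_count}); contigs absent from it simply
#'   have no hits.
#' @param weights marker weight table.
#' @param threshold density index above which a bin is a candidate
#'   (default 5.75).
#' @return data.frame with one row per bin: \code{bin_id},
#'   \code{genome_size}, \code{n_markers}, \code{weight_sum},
#'   \code{density_index} (NA when not evaluable), \code{evaluable},
#'   \code{is_candidate}; sorted by index descending (not-evaluable bins
#'   last).
#' @export
screen_bins <- function(bins, marker_hits,
                        weights = default_marker_weights(),
                        threshold = gv_config()$density_threshold) {
  need <- c("bin_id", "contig_id", "length")
  miss <- setdiff(need, names(bins))
  if (length(miss))
    stop("bin table misses column(s): ", paste(miss, collapse = ", "))
  if (nrow(bins) == 0L) stop("empty bin table")
  split_bins <- split(bins, bins$bin_id)
  res <- lapply(split_bins, function(b) {
    if (nrow(b) == 0L) stop("bin without contigs")
    size <- sum(b$length)
    hits <- marker_hits[marker_hits$contig_id %in% b$contig_id, ,
                        drop = FALSE]
    detected <- unique(hits$marker_id)
    detected <- intersect(detected, weights$marker_id)
    evaluable <- size > 10000
    idx <- if (evaluable)
      density_index(detected, weights, size) else NA_real_
    data.frame(bin_id = b$bin_id[1L],
               genome_size = as.integer(size),
               n_markers = length(detected),
               weight_sum = sum(weights$weight[
                 weights$marker_id %in% detected]),
               density_index = idx,
               evaluable = evaluable,
               is_candidate = if (evaluable) idx > threshold else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(!out$evaluable, -ifelse(is.na(out$density_index), -Inf,
                                           out$density_index),
                   out$bin_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
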