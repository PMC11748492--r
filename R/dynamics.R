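#' RPKM abundance normalisation
#'
#' Reads per kilobase of genome per million sequenced reads:
#' \code{count / ((length/1e3) * (library/1e6))}.
#'
#' @param read_counts integer matrix of mapped read counts (MAGs x
#'   samples).
#' @param mag_lengths named numeric vector of genome lengths in bp
#'   (> 0), covering the matrix rows.
#' @param library_sizes named numeric vector of total sequenced reads per
#'   sample (> 0), covering the matrix columns.
#' @return numeric matrix of RPKM values with the same dimnames.
#' @export
#' @examples
#' rpkm(matrix(1000, 1, 1, dimnames = list("m", "s")),
#'      c(m = 1e5), c(s = 1e7))
rpkm <- function(read_counts, mag_lengths, library_sizes) {
  read_counts <- as.matrix(read_counts)
  lens <- mag_lengths[rownames(read_counts)]
  libs <- library_sizes[colnames(read_counts)]
  if (anyNA(lens)) stop("missing genome length for some MAGs")
  if (anyNA(libs)) stop("missing library size for some samples")
  if (any(lens <= 0)) stop("genome lengths must be positive")
  if (any(libs <= 0)) stop("library sizes must be positive")
  sweep(sweep(read_counts, 1L, lens / 1e3, "/"), 2L, libs / 1e6, "/")
}

#' Presence call from coverage breadth
#'
#' A MAG is present in a sample only when its coverage breadth (fraction
#' of genome positions with at least one mapped read) strictly exceeds
#' the cutoff (default 0.5).
#'
#' @param breadth numeric vector in [0, 1].
#' @param cutoff strict breadth threshold (default 0.5).
#' @return logical vector.
#' @export
call_presence <- function(breadth, cutoff = gv_config()$breadth_presence) {
  if (any(breadth < 0 | breadth > 1)) stop("breadth must lie in [0, 1]")
  breadth > cutoff
}

#' Abundant MAGs of one sample by Simpson cumulation
#'
#' MAGs are sorted by relative abundance (descending, ties broken by id)
#' and accumulated until their summed squared relative abundances reach
#' the target fraction (default 80%) of the sample's total Simpson
#' concentration \eqn{\sum p_i^2}; the minimal such prefix is the abundant
#' set. The alternative reading (cumulate relative abundance itself) is
#' available via \code{rule = "abundance"}.
#'
#' @param sample_rpkm named numeric vector of RPKM values over MAGs for
#'   one sample.
#' @param fraction target cumulative fraction (default 0.80).
#' @param rule \code{"simpson"} (default) or \code{"abundance"}.
#' @return character vector of abundant MAG ids (empty, with a warning,
#'   when the sample has no signal).
#' @export
abundant_set <- function(sample_rpkm,
                         fraction = gv_config()$abundant_fraction,
                         rule = gv_config()$abundant_rule) {
  rule <- match.arg(rule, c("simpson", "abundance"))
  if (is.null(names(sample_rpkm))) stop("sample_rpkm must be named by MAG")
  if (any(sample_rpkm < 0)) stop("RPKM values must be non-negative")
  tot <- sum(sample_rpkm)
  if (tot == 0) {
    warning("all-zero sample: empty abundant set")
    return(character())
  }
  p <- sample_rpkm / tot
  ord <- order(-p, names(p))
  p <- p[ord]
  contrib <- if (rule == "simpson") p^2 else p
  target <- fraction * sum(contrib)
  k <- which(cumsum(contrib) >= target - 1e-12)[1L]
  names(p)[seq_len(k)]
}

#' Shannon and Simpson diversity of a community
#'
#' @param p numeric probability vector (non-negative, summing to 1).
#' @return list with \code{shannon} (\eqn{-\sum p \ln p}),
#'   \code{simpson} (the concentration \eqn{\sum p^2}, the quantity
#'   cumulated by \code{\link{abundant_set}}) and
#'   \code{simpson_diversity} (\eqn{1 - \sum p^2}).
#' @export
diversity_indices <- function(p) {
  if (any(p < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  shannon <- as.numeric(vegan::diversity(p, index = "shannon"))
  simpson_div <- as.numeric(vegan::diversity(p, index = "simpson"))
  list(shannon = shannon, simpson = 1 - simpson_div,
       simpson_diversity = simpson_div)
}

#' Sorensen-Dice similarity of two presence sets
#'
#' \code{2|a n b| / (|a| + |b|)}; the dissimilarity is one minus this.
#' Two empty communities are defined as identical (similarity 1, with a
#' warning).
#'
#' @param set_a,set_b character vectors of present MAG ids.
#' @return list with \code{similarity} and \code{dissimilarity}.
#' @export
sorensen_similarity <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0L && length(set_b) == 0L) {
    warning("both communities empty; similarity defined as 1")
    return(list(similarity = 1, dissimilarity = 0))
  }
  s <- 2 * length(intersect(set_a, set_b)) /
    (length(set_a) + length(set_b))
  list(similarity = s, dissimilarity = 1 - s)
}

#' Average a per-sample matrix into monthly bins
#'
#' Uneven sampling is evened out by binning samples into calendar months
#' and averaging every variable (abundances and environmental variables
#' alike) within each month.
#'
#' @param mat numeric matrix with samples as columns.
#' @param sample_table data.frame with \code{sample_id} and
#'   \code{month_key} (as from \code{\link{read_sample_table}}).
#' @return numeric matrix with one column per month key, in chronological
#'   order.
#' @export
monthly_binning <- function(mat, sample_table) {
  mat <- as.matrix(mat)
  keys <- sample_table$month_key[match(colnames(mat),
                                       sample_table$sample_id)]
  if (anyNA(keys)) stop("samples missing from the sample table: ",
                        paste(colnames(mat)[is.na(keys)], collapse = ", "))
  months <- sort(unique(keys))
  out <- vapply(months, function(m)
    rowMeans(mat[, keys == m, drop = FALSE]), numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), months))
  out
}

#' Community similarity versus time interval
#'
#' Emits every unordered pair of time points with its separation in days
#' and the Sorensen-Dice similarity of the two presence sets. No smoothing
#' is applied.
#'
#' @param presence logical matrix (MAGs x time points).
#' @param dates \code{Date} vector, one per column.
#' @return data.frame with \code{a}, \code{b}, \code{interval_days},
#'   \code{similarity} (n(n-1)/2 rows).
#' @export
similarity_timecourse <- function(presence, dates) {
  presence <- as.matrix(presence)
  n <- ncol(presence)
  if (n < 2L) stop("need at least 2 time points")
  if (length(dates) != n) stop("one date per column required")
  if (is.null(colnames(presence)))
    colnames(presence) <- paste0("t", seq_len(n))
  if (is.null(rownames(presence)))
    rownames(presence) <- paste0("m", seq_len(nrow(presence)))
  idx <- utils::combn(n, 2L)
  rows <- apply(idx, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    sa <- rownames(presence)[presence[, i]]
    sb <- rownames(presence)[presence[, j]]
    sim <- if (length(sa) == 0L && length(sb) == 0L) NA_real_
           else sorensen_similarity(sa, sb)$similarity
    c(interval_days = abs(as.numeric(dates[j] - dates[i])),
      similarity = sim)
  })
  data.frame(a = colnames(presence)[idx[1L, ]],
             b = colnames(presence)[idx[2L, ]],
             interval_days = rows["interval_days", ],
             similarity = rows["similarity", ],
             stringsAsFactors = FALSE)
}

# The fixed month axis of the two-year study design.
study_month_axis <- function() {
  c(sprintf("2017-%02d", 1:12), sprintf("2018-%02d", 1:9))
}

# longest run of TRUE in a logical vector
longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Niche classification of one MAG occurrence profile
#'
#' Classifies a MAG's monthly occurrence pattern over the January 2017 to
#' September 2018 axis into mutually exclusive niche categories, evaluated
#' in precedence order:
#' \enumerate{
#'   \item \code{excluded_2018_only}: never present in 2017.
#'   \item \code{persistent}: a run of strictly more than four (>= 5)
#'     consecutive present months fits inside at least one sliding
#'     8-month window (windows step by one month from Jan-Aug 2017 to
#'     Feb-Sep 2018).
#'   \item \code{seasonal}: all 2017 occurrences fit inside at least one
#'     8-month calendar window of 2017, the MAG reappears in at least one
#'     month of the same calendar window in 2018, and is absent in every
#'     observed 2018 month outside that window.
#'   \item \code{sporadic}: otherwise, with no 2018 occurrence.
#'   \item \code{other}: otherwise, with occurrences in both years.
#' }
#'
#' @param present named logical vector of monthly presence; names are
#'   YYYY-MM keys within the study axis.
#' @param window_len window length in months (default 8).
#' @return list with \code{label} and \code{evidence} (diagnostics:
#'   longest run, matching window months when seasonal).
#' @export
classify_niche <- function(present, window_len = gv_config()$niche_window) {
  axis <- study_month_axis()
  if (is.null(names(present)) || !all(names(present) %in% axis))
    stop("occurrence months must carry YYYY-MM names within the study",
         " axis (Jan 2017 - Sep 2018)")
  occ <- stats::setNames(rep(FALSE, length(axis)), axis)
  occ[names(present)] <- as.logical(present)
  m2017 <- occ[1:12]
  m2018 <- occ[13:21]
  if (!any(m2017))
    return(list(label = "excluded_2018_only",
                evidence = list(longest_run = longest_run(occ))))
  run <- longest_run(occ)
  if (run >= 5L)
    return(list(label = "persistent", evidence = list(longest_run = run)))
  # seasonal: candidate 8-month calendar windows fully inside 2017
  occ_months_2017 <- which(m2017)
  for (start in 1:(12 - window_len + 1L)) {
    win <- start:(start + window_len - 1L)
    if (!all(occ_months_2017 %in% win)) next
    win2018 <- intersect(win, 1:9)          # observed 2018 months
    inside <- any(m2018[win2018])
    outside <- any(m2018[setdiff(1:9, win2018)])
    if (inside && !outside)
      return(list(label = "seasonal",
                  evidence = list(longest_run = run,
                                  window = axis[win])))
  }
  if (!any(m2018))
    return(list(label = "sporadic", evidence = list(longest_run = run)))
  list(label = "other", evidence = list(longest_run = run))
}

#' Monthly relative-abundance profile of one MAG
#'
#' Normalises a MAG's monthly abundances to the fractions \eqn{p_i} used
#' by Levins' index: the share of the MAG's summed abundance falling in
#' month i.
#'
#' @param monthly_abundance named numeric vector (months).
#' @return named numeric vector summing to 1.
#' @export
occurrence_profile <- function(monthly_abundance) {
  if (any(monthly_abundance < 0)) stop("abundances must be non-negative")
  tot <- sum(monthly_abundance)
  if (tot == 0) stop("MAG has zero total abundance")
  monthly_abundance / tot
}

#' Levins' niche breadth index
#'
#' \eqn{B = 1 / \sum_i p_i^2} where \eqn{p_i} is the fraction of the
#' MAG's summed abundance in month i. B ranges from 1 (single-month
#' specialist) to n (uniform generalist over n months).
#'
#' @param p monthly relative abundances (non-negative, summing to 1).
#' @return numeric niche breadth.
#' @export
#' @examples
#' levins_index(c(0.8, 0.2))
levins_index <- function(p) {
  if (any(p < 0)) stop("relative abundances must be non-negative")
  if (sum(p) == 0) stop("Levins' index undefined for an all-zero profile")
  if (abs(sum(p) - 1) > 1e-9) stop("relative abundances must sum to 1")
  1 / sum(p^2)
}

#' Spearman correlation of a community metric with environmental variables
#'
#' Rank correlation per variable with Benjamini-Hochberg correction across
#' variables. Constant vectors are reported as not computable (NA) rather
#' than dropped.
#'
#' @param metric numeric vector (one value per sample).
#' @param env data.frame of numeric environmental variables aligned with
#'   \code{metric}.
#' @return data.frame with \code{variable}, \code{rho}, \code{p_value},
#'   \code{p_adj}, \code{n}.
#' @export
correlate_env <- function(metric, env) {
  env <- as.data.frame(env)
  if (nrow(env) != length(metric))
    stop("metric and environmental table lengths differ")
  rows <- lapply(names(env), function(v) {
    x <- env[[v]]
    ok <- stats::complete.cases(metric, x)
    if (sum(ok) < 4L)
      stop("variable '", v, "': fewer than 4 paired observations")
    if (stats::sd(x[ok]) == 0 || stats::sd(metric[ok]) == 0)
      return(data.frame(variable = v, rho = NA_real_, p_value = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(metric[ok], x[ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(variable = v, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("variable", "rho", "p_value", "p_adj", "n")]
}
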