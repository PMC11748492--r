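#' Default run configuration
#'
#' Collects every tunable threshold of the toolkit in one declarative list so
#' that pipeline stages never hard-code a constant. Values can be overridden
#' individually via \code{...} or loaded from a YAML file with
#' \code{\link{read_config}}.
#'
#' @param ... named overrides of individual defaults, e.g.
#'   \code{gv_config(density_threshold = 6)}.
#'
#' @return A named list with components:
#' \describe{
#'   \item{density_threshold}{core-gene density index above which a bin is a
#'     giant-virus candidate (default 5.75).}
#'   \item{marker_evalue}{HMM hit e-value cutoff (default 1e-10).}
#'   \item{score0_bin_fraction}{fraction of score-0 contigs above which a
#'     hallmark-free bin is discarded (default 0.90, strict).}
#'   \item{hallmark_genes}{the five NCLDV hallmark genes.}
#'   \item{single_copy_markers}{markers treated as single-copy when flagging
#'     chimeras (defaults to the hallmark genes).}
#'   \item{pc1_sd_limit}{tetranucleotide PC1 outlier bound in standard
#'     deviations (default 2.5).}
#'   \item{iqr_factor}{coverage outlier whisker multiplier (default 1.5).}
#'   \item{cov_cv_limit}{coverage coefficient of variation above which a bin
#'     is a chimera suspect (default 1).}
#'   \item{min_cluster_len}{minimum split-cluster length in bp (default 40000).}
#'   \item{score4_fraction}{fraction of contigs that must score 4 for a split
#'     cluster to be accepted (default 0.5, strict).}
#'   \item{species_consistency}{fraction of classified contigs that must share
#'     one species label in an accepted split cluster (default 0.8).}
#'   \item{ani_prescreen, ani_species}{dereplication ANI thresholds
#'     (defaults 0.90 and 0.95).}
#'   \item{sketch_k, sketch_size}{k-mer size and sketch size for the MinHash
#'     ANI estimator (defaults 21, 1000).}
#'   \item{red_threshold}{relative evolutionary divergence defining clades
#'     (default 0.65).}
#'   \item{core_fraction}{clade core-gene presence fraction, strict
#'     (default 0.5).}
#'   \item{breadth_presence}{coverage breadth above which a MAG is present,
#'     strict (default 0.5).}
#'   \item{abundant_fraction}{cumulative Simpson fraction defining the
#'     abundant set (default 0.80).}
#'   \item{abundant_rule}{"simpson" (cumulate squared relative abundances) or
#'     "abundance" (cumulate relative abundances).}
#'   \item{niche_window}{sliding occurrence window length in months
#'     (default 8).}
#'   \item{min_depth}{minimum per-site depth for SNV calling (default 5).}
#'   \item{min_alt_reads, min_alt_freq}{minor-allele support thresholds for
#'     SNV calling (defaults 2 reads, 0.05).}
#'   \item{shared_sites}{site universe for the fixation index: "union"
#'     (SNV in at least one sample, covered in both), "both", or
#'     "cocovered".}
#'   \item{rep_weights}{representative score weights for (log10 N50,
#'     log10 genome size, centrality); default c(1, 0.5, 1).}
#' }
#' @export
#' @examples
#' cfg <- gv_config(density_threshold = 6.0)
#' cfg$density_threshold
gv_config <- function(...) {
  cfg <- list(
    density_threshold   = 5.75,
    marker_evalue       = 1e-10,
    score0_bin_fraction = 0.90,
    hallmark_genes      = c("MCP", "PolB", "TFIIB", "TopoII", "A32"),
    single_copy_markers = c("MCP", "PolB", "TFIIB", "TopoII", "A32"),
    pc1_sd_limit        = 2.5,
    iqr_factor          = 1.5,
    cov_cv_limit        = 1,
    min_cluster_len     = 40000,
    score4_fraction     = 0.5,
    species_consistency = 0.8,
    ani_prescreen       = 0.90,
    ani_species         = 0.95,
    sketch_k            = 21L,
    sketch_size         = 1000L,
    red_threshold       = 0.65,
    core_fraction       = 0.5,
    breadth_presence    = 0.5,
    abundant_fraction   = 0.80,
    abundant_rule       = "simpson",
    niche_window        = 8L,
    min_depth           = 5L,
    min_alt_reads       = 2L,
    min_alt_freq        = 0.05,
    shared_sites        = "union",
    rep_weights         = c(n50 = 1, size = 0.5, centrality = 1)
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("configuration overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Read a configuration file
#'
#' Loads a YAML key-value file and merges it over the package defaults.
#'
#' @param path path to a YAML file whose top-level keys match
#'   \code{\link{gv_config}} names.
#' @return a configuration list as from \code{\link{gv_config}}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configuration requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  do.call(gv_config, vals)
}

# Machine-readable audit row used by every filtering decision.
gv_audit <- function(item, action, reason) {
  data.frame(item = as.character(item), action = as.character(action),
             reason = as.character(reason), stringsAsFactors = FALSE)
}

empty_audit <- function() gv_audit(character(), character(), character())
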