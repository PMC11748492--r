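#' Construct a candidate MAG (bin of contigs)
#'
#' A \code{gv_bin} bundles the per-contig evidence that the refinement cascade
#' operates on: lengths, the coverage used for outlier and chimera rules,
#' giant-virus characteristic scores, optional species labels, canonical
#' tetranucleotide profiles and marker-gene hits.
#'
#' @param bin_id character scalar, bin identifier.
#' @param contigs data.frame with columns \code{contig_id}, \code{length}
#'   (bp, > 0), \code{coverage} (mean mapping depth in the bin's source
#'   sample, >= 0) and optionally \code{char_score} (integer 0-4) and
#'   \code{species} (character, NA = unclassified).
#' @param tetra optional numeric matrix of canonical tetranucleotide
#'   frequencies (rows = contigs, 136 columns, each row summing to 1), row
#'   names matching \code{contig_id}.
#' @param markers optional data.frame with columns \code{contig_id},
#'   \code{marker_id}, \code{copy_count}.
#'
#' @return an object of class \code{gv_bin}.
#' @export
#' @examples
#' b <- gv_bin("bin1", data.frame(contig_id = c("c1", "c2"),
#'                                length = c(50000L, 60000L),
#'                                coverage = c(12, 14)))
#' genome_size(b)
gv_bin <- function(bin_id, contigs, tetra = NULL, markers = NULL) {
  stopifnot(is.character(bin_id), length(bin_id) == 1L)
  if (!is.data.frame(contigs) || nrow(contigs) == 0L)
    stop("bin '", bin_id, "' has no contigs")
  need <- c("contig_id", "length", "coverage")
  miss <- setdiff(need, names(contigs))
  if (length(miss))
    stop("contig table misses column(s): ", paste(miss, collapse = ", "))
  contigs$contig_id <- as.character(contigs$contig_id)
  if (anyDuplicated(contigs$contig_id))
    stop("duplicated contig ids in bin '", bin_id, "'")
  if (any(contigs$length <= 0)) stop("contig lengths must be positive")
  if (any(contigs$coverage < 0)) stop("contig coverages must be non-negative")
  if (is.null(contigs$char_score)) contigs$char_score <- NA_integer_
  ok <- is.na(contigs$char_score) |
    (contigs$char_score >= 0L & contigs$char_score <= 4L)
  if (!all(ok)) stop("characteristic scores must lie in [0, 4]")
  if (is.null(contigs$species)) contigs$species <- NA_character_
  if (!is.null(tetra)) {
    tetra <- as.matrix(tetra)
    if (is.null(rownames(tetra)) ||
        !all(contigs$contig_id %in% rownames(tetra)))
      stop("tetra matrix must carry row names covering all contigs")
    tetra <- tetra[contigs$contig_id, , drop = FALSE]
    sums <- rowSums(tetra)
    if (any(abs(sums - 1) > 1e-9))
      stop("tetranucleotide frequency rows must sum to 1")
  }
  if (!is.null(markers)) {
    stopifnot(all(c("contig_id", "marker_id", "copy_count") %in%
                    names(markers)))
    markers <- markers[markers$contig_id %in% contigs$contig_id, ,
                       drop = FALSE]
  }
  structure(list(bin_id = bin_id, contigs = contigs, tetra = tetra,
                 markers = markers),
            class = "gv_bin")
}

#' @export
print.gv_bin <- function(x, ...) {
  cat("<gv_bin>", x$bin_id, "-", nrow(x$contigs), "contigs,",
      genome_size(x), "bp\n")
  invisible(x)
}

#' Total genome size of a bin
#'
#' @param bin a \code{\link{gv_bin}}.
#' @return integer, the sum of member contig lengths in bp.
#' @export
genome_size <- function(bin) {
  stopifnot(inherits(bin, "gv_bin"))
  as.integer(sum(bin$contigs$length))
}

#' Hallmark genes present in a bin
#'
#' @param bin a \code{\link{gv_bin}} with marker hits attached.
#' @param hallmarks character vector of hallmark marker ids.
#' @return character vector, the subset of \code{hallmarks} with at least one
#'   hit in the bin.
#' @export
hallmark_present <- function(bin, hallmarks = gv_config()$hallmark_genes) {
  stopifnot(inherits(bin, "gv_bin"))
  if (is.null(bin$markers)) return(character())
  intersect(hallmarks, unique(bin$markers$marker_id))
}

#' Coverage coefficient of variation of a bin
#'
#' Standard deviation over mean of the member contigs' coverages (the
#' across-contig reading; chimeric bins mixing genomes at different
#' abundances show a high value).
#'
#' @param bin a \code{\link{gv_bin}}.
#' @return numeric scalar sd/mean.
#' @export
cov_cv <- function(bin) {
  stopifnot(inherits(bin, "gv_bin"))
  cv <- bin$contigs$coverage
  m <- mean(cv)
  if (m == 0) stop("coverage CV undefined: bin '", bin$bin_id,
                   "' has zero mean coverage")
  stats::sd(cv) / m
}

# ---- canonical tetranucleotides -------------------------------------------

# Names of the 136 canonical (reverse-complement collapsed) 4-mers, and the
# mapping from all 256 4-mers onto them.
tetra_canonical_map <- function() {
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(bases, bases, bases, bases,
                                       stringsAsFactors = FALSE)[, 4:1])
  rc <- vapply(strsplit(chartr("ACGT", "TGCA", kmers), ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  canon <- pmin(kmers, rc)
  names(canon) <- kmers
  canon
}

#' Canonical tetranucleotide frequencies
#'
#' Counts forward-strand 4-mers and collapses each with its reverse
#' complement, yielding 136 canonical frequencies per sequence that sum to 1.
#' This is the composition space used for contamination screening and
#' chimera splitting.
#'
#' @param seqs a \code{Biostrings::DNAStringSet} (or character vector of DNA
#'   sequences, possibly named).
#' @return numeric matrix, one row per sequence, 136 canonical 4-mer columns.
#' @export
#' @examples
#' tetra_frequencies(c(c1 = "ACGTACGTACGTACGTACGT"))
tetra_frequencies <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = 4)
  canon <- tetra_canonical_map()
  groups <- canon[colnames(counts)]
  agg <- t(rowsum(t(counts), group = groups))
  freq <- agg / pmax(rowSums(agg), 1L)
  rownames(freq) <- names(seqs)
  freq
}
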