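# ---- k-mer hashing ---------------------------------------------------------

# Modulus and scrambling constants for the rolling canonical k-mer hash.
# The prime is < 2^26 so that h*4 + c stays exactly representable in a
# double; hash quality only needs to be good enough for sketching.
.KMER_PRIME <- 67108859
.KMER_MIX_A <- 2654435

# Canonical (strand-collapsed) k-mer hash values of one DNA string.
# Returns the per-window min of the forward and reverse-complement rolling
# hashes; windows containing non-ACGT characters are dropped.
kmer_hashes <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k (", n, " < ", k, ")")
  code <- integer(256)
  code[] <- NA_integer_
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  code[utf8ToInt("a")] <- 0L; code[utf8ToInt("c")] <- 1L
  code[utf8ToInt("g")] <- 2L; code[utf8ToInt("t")] <- 3L
  codes <- code[utf8ToInt(seq)]
  nw <- n - k + 1L
  roll <- function(cd) {
    h <- numeric(length(cd) - k + 1L)
    for (j in seq_len(k))
      h <- (h * 4 + cd[j:(j + length(h) - 1L)]) %% .KMER_PRIME
    h
  }
  ok <- !is.na(codes)
  if (!all(ok)) {
    # mask windows overlapping ambiguity codes
    bad_win <- unique(unlist(lapply(which(!ok), function(i)
      max(1L, i - k + 1L):min(nw, i))))
    codes[is.na(codes)] <- 0L
  } else bad_win <- integer()
  hf <- roll(codes)
  hr <- rev(roll(rev(3L - codes)))
  h <- pmin(hf, hr)
  if (length(bad_win)) h <- h[-bad_win]
  (h * .KMER_MIX_A + 1) %% .KMER_PRIME
}

# Canonical k-mer hash set of a genome (one or more contigs).
genome_hash_set <- function(genome, k) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  genome <- genome[nchar(genome) >= k]
  if (length(genome) == 0L)
    stop("genome shorter than k = ", k)
  unique(unlist(lapply(genome, kmer_hashes, k = k), use.names = FALSE))
}

#' MinHash sketch ANI estimate
#'
#' Rapid ANI estimation in the Mash style: both genomes are reduced to
#' bottom-s sketches of canonical k-mer hashes, the Jaccard index j is
#' estimated from the merged sketch, and identity recovered through the
#' Mash distance transform \eqn{\mathrm{ANI} = 1 + \ln(2j/(1+j))/k}. The
#' hash function is fixed, so the estimate is fully deterministic.
#'
#' @param genome_a,genome_b DNA sequences (character vector of contigs or
#'   \code{DNAStringSet}), each at least k bp.
#' @param k k-mer size (default 21).
#' @param sketch_size sketch size s (default 1000).
#' @return list with \code{jaccard}, \code{ani} (0 when no k-mers are
#'   shared; such pairs are effectively unrelated), \code{related}
#'   (jaccard > 0) and \code{method = "sketch"}.
#' @export
sketch_ani <- function(genome_a, genome_b, k = gv_config()$sketch_k,
                       sketch_size = gv_config()$sketch_size) {
  ha <- genome_hash_set(genome_a, k)
  hb <- genome_hash_set(genome_b, k)
  sa <- sort(ha)[seq_len(min(sketch_size, length(ha)))]
  sb <- sort(hb)[seq_len(min(sketch_size, length(hb)))]
  s <- min(sketch_size, length(ha), length(hb))
  merged <- sort(unique(c(sa, sb)))[seq_len(min(s, length(unique(c(sa, sb)))))]
  shared <- sum(merged %in% sa & merged %in% sb)
  j <- shared / length(merged)
  ani <- if (j > 0) max(0, 1 + log(2 * j / (1 + j)) / k) else 0
  list(jaccard = j, ani = ani, related = j > 0, method = "sketch")
}

#' Containment-based precise ANI estimate
#'
#' The default precise backend for species-level clustering: the canonical
#' k-mer containment \eqn{C = |A \cap B| / \min(|A|,|B|)} estimates the
#' probability that a k-mer window is free of differences, so
#' \eqn{\mathrm{ANI} = C^{1/k}}. Using the smaller set in the denominator
#' makes the estimate robust to incomplete genomes, in the spirit of
#' best-fragment alignment ANI.
#'
#' @param genome_a,genome_b DNA sequences as in \code{\link{sketch_ani}}.
#' @param k k-mer size (default 21).
#' @return list with \code{containment}, \code{ani}, \code{method}.
#' @export
containment_ani <- function(genome_a, genome_b, k = gv_config()$sketch_k) {
  ha <- genome_hash_set(genome_a, k)
  hb <- genome_hash_set(genome_b, k)
  cont <- length(intersect(ha, hb)) / min(length(ha), length(hb))
  list(containment = cont, ani = cont^(1 / k), method = "containment")
}

#' Pairwise ANI matrix
#'
#' @param genomes named list of genomes (each a character vector of contigs
#'   or a \code{DNAStringSet}).
#' @param ani_fn pairwise estimator returning a list with an \code{ani}
#'   component (default \code{\link{containment_ani}}).
#' @param ... passed to \code{ani_fn}.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
ani_matrix <- function(genomes, ani_fn = containment_ani, ...) {
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids))) stop("genomes must be named")
  n <- length(genomes)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- ani_fn(genomes[[i]], genomes[[j]], ...)$ani
      m[i, j] <- m[j, i] <- a
    }
  m
}

# Connected components of an undirected adjacency matrix (single linkage).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Cluster genomes at the species boundary
#'
#' Two-stage dereplication clustering: a fast sketch-ANI prescreen groups
#' genomes into coarse components by single linkage at the prescreen
#' threshold (default 90% ANI), then each component is subclustered by
#' average linkage on precise-ANI distances, cut so that cluster members
#' share at least the species threshold (default 95% ANI).
#'
#' @param genomes named list of genomes.
#' @param prescreen coarse single-linkage ANI threshold (default 0.90).
#' @param species species-level average-linkage ANI threshold
#'   (default 0.95).
#' @param ani_fn precise backend (default \code{\link{containment_ani}});
#'   pluggable so an external aligner can be hooked in.
#' @param config configuration list (sketch parameters).
#' @return list with \code{clusters} (data.frame \code{genome_id},
#'   \code{cluster}) and \code{ani} (precise ANI matrix, computed within
#'   prescreen components, NA elsewhere).
#' @export
cluster_genomes <- function(genomes, prescreen = gv_config()$ani_prescreen,
                            species = gv_config()$ani_species,
                            ani_fn = containment_ani,
                            config = gv_config()) {
  ids <- sort(names(genomes))
  genomes <- genomes[ids]
  n <- length(genomes)
  sketch <- ani_matrix(genomes, sketch_ani, k = config$sketch_k,
                       sketch_size = config$sketch_size)
  comp <- graph_components(sketch >= prescreen)
  precise <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(precise) <- 1
  cluster <- integer(n)
  names(cluster) <- ids
  nxt <- 0L
  for (cp in sort(unique(comp))) {
    members <- ids[comp == cp]
    if (length(members) == 1L) {
      nxt <- nxt + 1L
      cluster[members] <- nxt
      next
    }
    sub <- ani_matrix(genomes[members], ani_fn)
    precise[members, members] <- sub
    d <- stats::as.dist(1 - sub)
    hc <- stats::hclust(d, method = "average")
    sub_cl <- stats::cutree(hc, h = 1 - species)
    cluster[members] <- nxt + sub_cl
    nxt <- nxt + max(sub_cl)
  }
  list(clusters = data.frame(genome_id = ids, cluster = as.integer(cluster),
                             stringsAsFactors = FALSE),
       ani = precise)
}

#' N50 of a set of contig lengths
#'
#' @param lengths integer vector of contig lengths in bp.
#' @return the N50 length in bp.
#' @export
n50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1L]]
}

#' Choose a cluster representative
#'
#' Scores each member as \code{log10(N50) + 0.5 log10(genome size) +
#' centrality} (centrality = mean precise ANI to the other members; 1 for a
#' singleton) and returns the arg-max; exact ties break to the
#' lexicographically smaller genome id.
#'
#' @param members character vector of genome ids in one cluster.
#' @param stats_df data.frame with columns \code{genome_id}, \code{n50},
#'   \code{genome_size}.
#' @param ani precise ANI matrix covering the members.
#' @param weights numeric length-3 weights for (log10 N50, log10 size,
#'   centrality).
#' @return list with \code{representative} (genome id) and \code{scores}
#'   (named numeric vector).
#' @export
choose_representative <- function(members, stats_df, ani,
                                  weights = gv_config()$rep_weights) {
  stopifnot(length(members) >= 1L)
  rows <- stats_df[match(members, stats_df$genome_id), , drop = FALSE]
  if (anyNA(rows$genome_id))
    stop("missing genome stats for: ",
         paste(setdiff(members, stats_df$genome_id), collapse = ", "))
  centrality <- vapply(members, function(g) {
    others <- setdiff(members, g)
    if (length(others) == 0L) 1 else mean(ani[g, others])
  }, numeric(1))
  score <- weights[[1L]] * log10(rows$n50) +
    weights[[2L]] * log10(rows$genome_size) + weights[[3L]] * centrality
  names(score) <- members
  ord <- order(-score, members)
  list(representative = members[ord[1L]], scores = score)
}

#' Dereplicate a genome collection
#'
#' End-to-end wrapper: clusters genomes at the species boundary
#' (\code{\link{cluster_genomes}}) and picks the best-scoring
#' representative of each cluster.
#'
#' @param genomes named list of genomes (character contig vectors or
#'   \code{DNAStringSet}s).
#' @param ... passed to \code{\link{cluster_genomes}}.
#' @return list with \code{clusters} (data.frame \code{genome_id},
#'   \code{cluster}, \code{representative} flag), \code{representatives}
#'   (character vector) and \code{ani} (precise ANI matrix).
#' @export
dereplicate_genomes <- function(genomes, ...) {
  if (methods::is(genomes, "DNAStringSet"))
    genomes <- as.list(as.character(genomes))
  cl <- cluster_genomes(genomes, ...)
  lens <- lapply(genomes, function(g) {
    if (methods::is(g, "DNAStringSet")) g <- as.character(g)
    nchar(g)
  })
  stats_df <- data.frame(
    genome_id = names(genomes),
    n50 = vapply(lens, n50, numeric(1)),
    genome_size = vapply(lens, sum, numeric(1)),
    stringsAsFactors = FALSE)
  reps <- vapply(split(cl$clusters$genome_id, cl$clusters$cluster),
                 function(members)
                   choose_representative(members, stats_df,
                                         cl$ani)$representative,
                 character(1))
  cl$clusters$representative <- cl$clusters$genome_id %in% reps
  list(clusters = cl$clusters, representatives = unname(reps), ani = cl$ani)
}
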