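# Node labels used in RED maps: tip labels for leaves, "node_<k>" (or the
# tree's own node labels when present and unique) for internal nodes.
node_ids <- function(tree) {
  internal <- if (!is.null(tree$node.label) &&
                  !anyDuplicated(tree$node.label) &&
                  all(nzchar(tree$node.label)))
    tree$node.label
  else paste0("node_", seq_len(tree$Nnode))
  c(tree$tip.label, internal)
}

#' Relative evolutionary divergence of every node
#'
#' Computes RED on a rooted tree with branch lengths by the standard
#' root-to-tip recursion: \code{red(root) = 0}; for a child at branch
#' distance d from its parent with mean node-to-descendant-tip distance u,
#' \code{red(child) = red(parent) + d/(d+u) * (1 - red(parent))}; every
#' leaf has RED 1. Values interpolate node depth between the root (0) and
#' the leaves (1), making clade-defining thresholds comparable across
#' lineages.
#'
#' @param tree a rooted \code{ape::phylo} with non-negative branch lengths
#'   and at least 2 leaves.
#' @return named numeric vector of RED values over all nodes (tips first,
#'   then internal nodes; see node naming above).
#' @export
red_values <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 leaves")
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  # mean distance from each node to its descendant tips
  depth <- ape::node.depth.edgelength(tree)      # root-to-node distance
  u <- numeric(nnode)
  ntips_below <- integer(nnode)
  sumdist <- numeric(nnode)
  ntips_below[seq_len(ntip)] <- 1L
  sumdist[seq_len(ntip)] <- 0
  edge <- tree$edge
  # postorder accumulation of tip counts and summed tip distances
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    ntips_below[p] <- ntips_below[p] + ntips_below[ch]
    sumdist[p] <- sumdist[p] + sumdist[ch] +
      ntips_below[ch] * tree$edge.length[i]
  }
  u <- sumdist / ntips_below
  red <- numeric(nnode)
  red[root] <- 0
  # preorder: ape's default edge order is compatible (cladewise)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    d <- ord$edge.length[i]
    red[ch] <- if (d + u[ch] > 0)
      red[p] + d / (d + u[ch]) * (1 - red[p]) else red[p]
  }
  red[seq_len(ntip)] <- 1
  stats::setNames(red, node_ids(tree))
}

#' Delimit clades on a rooted tree by a RED threshold
#'
#' A clade is the maximal subtree whose root is an internal node with
#' RED at or above the threshold while its parent is below it. Leaves not
#' covered by any such subtree (typically long branches hanging directly
#' off deep nodes) are returned as unassessed rather than forced into a
#' clade.
#'
#' @param tree rooted \code{ape::phylo}.
#' @param red named RED vector from \code{\link{red_values}} (recomputed
#'   when NULL).
#' @param threshold clade-defining RED value (default 0.65). A threshold
#'   of 0 yields a single clade containing every leaf.
#' @return list with \code{clades} (named list: clade id -> character
#'   vector of member tips) and \code{unassessed} (character vector of
#'   tips).
#' @export
define_clades <- function(tree, red = NULL,
                          threshold = gv_config()$red_threshold) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(red)) red <- red_values(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ids <- node_ids(tree)
  if (!all(ids %in% names(red))) stop("red map does not cover all nodes")
  red <- red[ids]
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  is_root_node <- internal == root
  qualifies <- red[internal] >= threshold &
    (is_root_node | red[parent[internal]] < threshold)
  clade_roots <- internal[qualifies]
  tip_sets <- lapply(clade_roots, function(nd) {
    tree$tip.label[phangorn_descendants(tree, nd)]
  })
  names(tip_sets) <- ids[clade_roots]
  assessed <- unlist(tip_sets, use.names = FALSE)
  list(clades = tip_sets,
       unassessed = setdiff(tree$tip.label, assessed))
}

# Tip indices descending from an internal node (iterative, no deps).
phangorn_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(stack, children[[as.character(v)]])
  }
  sort(out)
}

#' Core genes and modal copy numbers of a clade
#'
#' Core orthologous groups are those present in strictly more than half of
#' the clade members. For each core OG the modal positive copy number among
#' the members possessing it is recorded; a tie in the mode breaks to the
#' smaller copy number.
#'
#' @param og_table data.frame (\code{genome_id}, \code{og_id},
#'   \code{copy_count}).
#' @param members character vector of clade member genome ids (>= 2).
#' @param core_fraction strict presence fraction (default 0.5).
#' @return list with \code{members}, \code{core_ogs} (character) and
#'   \code{mode_copy} (named integer over core OGs).
#' @export
clade_core <- function(og_table, members,
                       core_fraction = gv_config()$core_fraction) {
  if (length(members) == 0L) stop("empty clade")
  if (length(members) < 2L)
    stop("clade core genes require at least 2 members")
  sub <- og_table[og_table$genome_id %in% members, , drop = FALSE]
  presence <- tapply(sub$genome_id, sub$og_id,
                     function(g) length(unique(g)))
  core <- names(presence)[presence / length(members) > core_fraction]
  mode_copy <- vapply(core, function(og) {
    copies <- sub$copy_count[sub$og_id == og]
    tab <- table(copies)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)
  }, integer(1))
  list(members = members, core_ogs = sort(core),
       mode_copy = mode_copy[sort(core)])
}

#' Consistency and redundancy of one MAG against its clade
#'
#' Consistency is the fraction of the clade's core OGs found in the genome.
#' Redundancy counts excess gene copies over the clade modal copy number,
#' summed over core OGs and normalised by the number of core OGs the
#' genome possesses. A genome holding no core OG gets consistency 0 and an
#' undefined (NA) redundancy, flagged.
#'
#' @param genome_id genome to score (must appear in \code{og_table}).
#' @param og_table data.frame (\code{genome_id}, \code{og_id},
#'   \code{copy_count}).
#' @param clade clade description from \code{\link{clade_core}}.
#' @return data.frame row: \code{genome_id}, \code{n_core},
#'   \code{n_core_present}, \code{consistency}, \code{redundant_copies},
#'   \code{redundancy}, \code{flag}.
#' @export
score_mag <- function(genome_id, og_table, clade) {
  g <- og_table[og_table$genome_id == genome_id, , drop = FALSE]
  if (nrow(g) == 0L)
    stop("genome '", genome_id, "' absent from the OG table")
  core <- clade$core_ogs
  copies <- stats::setNames(g$copy_count, g$og_id)[core]
  copies[is.na(copies)] <- 0L
  present <- copies > 0L
  n_present <- sum(present)
  consistency <- if (length(core)) n_present / length(core) else NA_real_
  excess <- pmax(0L, copies - clade$mode_copy)
  if (n_present == 0L) {
    redundancy <- NA_real_
    flag <- "no_core_genes"
  } else {
    redundancy <- sum(excess[present]) / n_present
    flag <- ""
  }
  data.frame(genome_id = genome_id, n_core = length(core),
             n_core_present = n_present,
             consistency = if (length(core)) consistency else 0,
             redundant_copies = as.integer(sum(excess)),
             redundancy = redundancy, flag = flag,
             stringsAsFactors = FALSE)
}

#' Phylogeny-informed MAG assessment
#'
#' End-to-end quality assessment: RED values are computed on the guide
#' tree, clades delimited at the RED threshold, clade core genes derived
#' from the OG table, and every clade member scored for consistency and
#' redundancy. Genomes on long branches (no clade) and members of
#' single-genome clades are reported as unassessed.
#'
#' @param tree rooted guide tree (\code{ape::phylo}) whose tips are genome
#'   ids.
#' @param og_table data.frame (\code{genome_id}, \code{og_id},
#'   \code{copy_count}).
#' @param threshold RED clade threshold (default 0.65).
#' @param core_fraction strict core presence fraction (default 0.5).
#' @return list with \code{scores} (data.frame of per-genome scores plus
#'   \code{clade_id}), \code{clades} (from \code{\link{define_clades}}),
#'   \code{unassessed} (character vector).
#' @export
pima_assess <- function(tree, og_table,
                        threshold = gv_config()$red_threshold,
                        core_fraction = gv_config()$core_fraction) {
  red <- red_values(tree)
  cl <- define_clades(tree, red, threshold)
  unassessed <- cl$unassessed
  rows <- list()
  for (cid in names(cl$clades)) {
    members <- cl$clades[[cid]]
    members <- intersect(members, unique(og_table$genome_id))
    if (length(members) < 2L) {
      unassessed <- union(unassessed, cl$clades[[cid]])
      next
    }
    core <- clade_core(og_table, members, core_fraction)
    sc <- do.call(rbind, lapply(members, score_mag, og_table = og_table,
                                clade = core))
    sc$clade_id <- cid
    rows[[cid]] <- sc
  }
  scores <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(scores)) rownames(scores) <- NULL
  list(scores = scores, clades = cl$clades, unassessed = unassessed)
}
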