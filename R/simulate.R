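# ---- seeding ---------------------------------------------------------------

# Stable per-entity substream seed: a small string hash folded into the base
# seed, so adding one entity never shifts another entity's draws.
sub_seed <- function(seed, key) {
  h <- 5381
  for (cc in utf8ToInt(as.character(key))) h <- (h * 33 + cc) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

# Expected canonical tetranucleotide profile of an iid base model.
expected_tetra <- function(base_freq) {
  canon <- tetra_canonical_map()
  bases <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  kmers <- names(canon)
  probs <- vapply(strsplit(kmers, ""), function(b)
    prod(base_freq[bases[b]]), numeric(1))
  agg <- tapply(probs, canon, sum)
  agg[sort(unique(canon))]
}

# Random DNA sequence under an iid base model.
random_dna <- function(n, base_freq = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = base_freq),
        collapse = "")
}

# ---- contig community ------------------------------------------------------

#' Simulate a binned contig community with planted ground truth
#'
#' Generates everything the screening and refinement stages consume: a bin
#' membership table, per-contig coverages across samples, canonical
#' tetranucleotide profiles, marker-gene hits, classifier verdicts and HMM
#' hits, together with a truth table labelling every contig. Viral bins
#' (100 kb - 1 Mb) carry all 20 marker genes and high classifier agreement;
#' cellular bins (2 - 6 Mb) carry at most 2 non-hallmark markers and score
#' 0 throughout; planted contaminant contigs inside viral bins combine
#' deviant coverage and composition with characteristic scores of 0 or 1;
#' chimera bins concatenate two viral genomes at different abundances.
#' Composition is modelled directly in tetranucleotide space: each genome
#' gets an iid base model whose expected canonical 4-mer profile anchors
#' tight per-contig Dirichlet draws; contig sequences, when requested, are
#' drawn from the same base model.
#'
#' @param n_viral,n_cellular,n_chimera numbers of planted bins.
#' @param contaminant_frac fraction of contigs added to each viral bin as
#'   contaminants (default 0).
#' @param n_samples number of coverage samples (default 4).
#' @param sequences also emit contig sequences as a
#'   \code{Biostrings::DNAStringSet} (default FALSE; sizes are then kept
#'   as planted lengths without materialising multi-Mb strings).
#' @param seed integer seed; identical parameters plus seed give
#'   identical output.
#' @return list with \code{bins} (bin_id, contig_id, length),
#'   \code{contigs} (per-contig metadata: coverage, char_score, species),
#'   \code{depth} (depth table as from \code{\link{read_depth_table}}),
#'   \code{tetra} (matrix), \code{marker_hits}, \code{verdicts},
#'   \code{hmm_hit_contigs}, \code{truth} (contig_id, bin_id, role,
#'   source_genome), optionally \code{seqs}.
#' @export
sim_community <- function(n_viral = 5, n_cellular = 5, n_chimera = 0,
                          contaminant_frac = 0, n_samples = 4,
                          sequences = FALSE, seed = 1) {
  if (n_viral < 0 || n_cellular < 0 || n_chimera < 0 ||
      contaminant_frac < 0 || contaminant_frac >= 1)
    stop("infeasible community parameters")
  markers <- list()
  marker_ids <- default_marker_weights()$marker_id
  tools <- paste0("tool", 1:3)

  add_contig <- function(env, bin_id, contig_id, len, covs, score, species,
                         role, source, base_freq, conc = 20000) {
    profile <- expected_tetra(base_freq)
    tt <- rdirichlet1(conc * profile)
    env$contigs[[contig_id]] <- data.frame(
      contig_id = contig_id, bin_id = bin_id, length = as.integer(len),
      coverage = covs[1L], char_score = as.integer(score),
      species = species, stringsAsFactors = FALSE)
    env$cov[[contig_id]] <- covs
    env$tetra[[contig_id]] <- tt
    env$truth[[contig_id]] <- data.frame(
      contig_id = contig_id, bin_id = bin_id, role = role,
      source_genome = source, stringsAsFactors = FALSE)
    if (sequences)
      env$seqs[[contig_id]] <- random_dna(len, base_freq)
    # classifier verdicts and hmm hit consistent with the planted score
    n_target <- max(0L, min(3L, score - 1L))
    hmm <- score >= 1L
    v <- rep("other", 3L)
    if (n_target > 0L) v[seq_len(n_target)] <- "target_lineage"
    env$verdicts[[contig_id]] <- data.frame(
      contig_id = contig_id, tool_name = tools, verdict = v,
      stringsAsFactors = FALSE)
    if (hmm) env$hmm <- c(env$hmm, contig_id)
    invisible(NULL)
  }

  env <- new.env()
  env$contigs <- list(); env$cov <- list(); env$tetra <- list()
  env$truth <- list(); env$verdicts <- list(); env$seqs <- list()
  env$hmm <- character()
  place_markers <- function(bin_contig_ids, which_markers, env) {
    on_contig <- sample(bin_contig_ids, length(which_markers),
                        replace = TRUE)
    data.frame(contig_id = on_contig, marker_id = which_markers,
               e_value = 1e-20, copy_count = 1L, stringsAsFactors = FALSE)
  }

  viral_genome <- function(bin_id, cov_mu, base_freq, n_contig, total_len,
                           species, contam = 0) {
    lens <- pmax(2500L, as.integer(rdirichlet1(rep(2, n_contig)) *
                                     total_len))
    covs_bin <- cov_mu * exp(stats::rnorm(n_samples, 0, 0.3))
    ids <- sprintf("%s_c%02d", bin_id, seq_len(n_contig))
    for (i in seq_len(n_contig)) {
      covs <- covs_bin * exp(stats::rnorm(n_samples, 0, 0.05))
      # most viral contigs score 4; a minority scores 2-3, none below 2
      score <- sample(c(4L, 4L, 4L, 3L, 2L), 1L)
      add_contig(env, bin_id, ids[i], lens[i], covs, score, species,
                 "viral", bin_id, base_freq)
    }
    mk <- place_markers(ids, marker_ids, env)
    n_contam <- round(contam * n_contig)
    if (n_contam > 0) {
      cfreq <- rdirichlet1(c(10, 30, 30, 10))   # deviant GC-rich model
      for (j in seq_len(n_contam)) {
        cid <- sprintf("%s_x%02d", bin_id, j)
        covs <- covs_bin * 10 * exp(stats::rnorm(n_samples, 0, 0.05))
        score <- if (j %% 2 == 0) 0L else 1L
        add_contig(env, bin_id, cid, 3000L + j * 100L, covs, score,
                   NA_character_, "contaminant", "cellular_src", cfreq,
                   conc = 20000)
      }
    }
    mk
  }

  for (v in seq_len(n_viral)) {
    bid <- sprintf("viral_%02d", v)
    markers[[bid]] <- with_seed(sub_seed(seed, bid), {
      total_len <- round(stats::runif(1, 1e5, 1e6))
      base_freq <- rdirichlet1(c(30, 20, 20, 30))   # AT-leaning viral model
      viral_genome(bid, cov_mu = exp(stats::rnorm(1, 3, 0.5)),
                   base_freq = base_freq,
                   n_contig = sample(8:15, 1), total_len = total_len,
                   species = sprintf("species_%02d", v),
                   contam = contaminant_frac)
    })
  }
  for (cbin in seq_len(n_cellular)) {
    bid <- sprintf("cell_%02d", cbin)
    markers[[bid]] <- with_seed(sub_seed(seed, bid), {
      total_len <- round(stats::runif(1, 2e6, 6e6))
      base_freq <- rdirichlet1(c(20, 30, 30, 20))
      n_contig <- sample(20:40, 1)
      lens <- pmax(2500L, as.integer(rdirichlet1(rep(2, n_contig)) *
                                       total_len))
      covs_bin <- exp(stats::rnorm(1, 3, 0.5)) *
        exp(stats::rnorm(n_samples, 0, 0.3))
      ids <- sprintf("%s_c%02d", bid, seq_len(n_contig))
      for (i in seq_len(n_contig)) {
        covs <- covs_bin * exp(stats::rnorm(n_samples, 0, 0.05))
        add_contig(env, bid, ids[i], lens[i], covs, 0L, NA_character_,
                   "cellular", bid, base_freq)
      }
      n_mk <- sample(0:2, 1)
      if (n_mk > 0)
        place_markers(ids,
                      sample(setdiff(marker_ids,
                                     gv_config()$hallmark_genes), n_mk),
                      env)
      else NULL
    })
  }
  for (ch in seq_len(n_chimera)) {
    bid <- sprintf("chimera_%02d", ch)
    markers[[bid]] <- with_seed(sub_seed(seed, bid), {
      # two genomes at very different abundances; the low-coverage genome
      # contributes more contigs so that the coverage CV exceeds 1
      fA <- rdirichlet1(c(40, 15, 15, 40))
      fB <- rdirichlet1(c(15, 40, 40, 15))
      nA <- 10L; nB <- 4L
      lensA <- rep(12000L, nA); lensB <- rep(25000L, nB)
      idsA <- sprintf("%s_a%02d", bid, seq_len(nA))
      idsB <- sprintf("%s_b%02d", bid, seq_len(nB))
      for (i in seq_len(nA))
        add_contig(env, bid, idsA[i], lensA[i],
                   10 * exp(stats::rnorm(n_samples, 0, 0.02)), 4L,
                   "species_A", "chimera_partA", paste0(bid, "_A"), fA)
      for (i in seq_len(nB))
        add_contig(env, bid, idsB[i], lensB[i],
                   200 * exp(stats::rnorm(n_samples, 0, 0.02)), 4L,
                   "species_B", "chimera_partB", paste0(bid, "_B"), fB)
      rbind(place_markers(idsA, marker_ids, env),
            place_markers(idsB, marker_ids, env))
    })
  }
  markers <- Filter(Negate(is.null), markers)

  contig_df <- do.call(rbind, env$contigs)
  rownames(contig_df) <- NULL
  covm <- do.call(rbind, env$cov)
  colnames(covm) <- sprintf("S%02d", seq_len(n_samples))
  rownames(covm) <- contig_df$contig_id
  tetra_m <- do.call(rbind, env$tetra)
  rownames(tetra_m) <- contig_df$contig_id
  depth <- data.frame(contig_id = contig_df$contig_id,
                      contig_len = contig_df$length,
                      stringsAsFactors = FALSE)
  for (s in colnames(covm)) depth[[s]] <- covm[, s]
  attr(depth, "samples") <- colnames(covm)
  marker_df <- do.call(rbind, c(markers, list(
    data.frame(contig_id = character(), marker_id = character(),
               e_value = numeric(), copy_count = integer(),
               stringsAsFactors = FALSE))))
  rownames(marker_df) <- NULL
  # aggregate duplicate (contig, marker) placements into copy counts
  if (nrow(marker_df)) {
    key <- paste(marker_df$contig_id, marker_df$marker_id, sep = "\r")
    first <- !duplicated(key)
    cnt <- tapply(marker_df$copy_count, key, sum)
    marker_df <- data.frame(contig_id = marker_df$contig_id[first],
                            marker_id = marker_df$marker_id[first],
                            e_value = 1e-20,
                            copy_count = as.integer(cnt[key[first]]),
                            stringsAsFactors = FALSE)
  }
  verdict_df <- do.call(rbind, env$verdicts)
  rownames(verdict_df) <- NULL
  truth_df <- do.call(rbind, env$truth)
  rownames(truth_df) <- NULL
  out <- list(
    bins = contig_df[, c("bin_id", "contig_id", "length")],
    contigs = contig_df,
    cov = covm,
    depth = depth,
    tetra = tetra_m,
    marker_hits = marker_df,
    verdicts = verdict_df,
    hmm_hit_contigs = env$hmm,
    truth = truth_df)
  if (sequences) {
    ss <- Biostrings::DNAStringSet(unlist(env$seqs))
    names(ss) <- names(env$seqs)
    out$seqs <- ss
  }
  out
}

#' Assemble gv_bin objects from a simulated community
#'
#' @param community output of \code{\link{sim_community}}.
#' @return named list of \code{\link{gv_bin}} objects.
#' @export
community_bins <- function(community) {
  ids <- unique(community$contigs$bin_id)
  out <- lapply(ids, function(bid) {
    sub <- community$contigs[community$contigs$bin_id == bid, , drop = FALSE]
    gv_bin(bid,
           data.frame(contig_id = sub$contig_id, length = sub$length,
                      coverage = sub$coverage, char_score = sub$char_score,
                      species = sub$species, stringsAsFactors = FALSE),
           tetra = community$tetra[sub$contig_id, , drop = FALSE],
           markers = community$marker_hits[
             community$marker_hits$contig_id %in% sub$contig_id, ,
             drop = FALSE])
  })
  stats::setNames(out, ids)
}

# ---- SNV profiles ----------------------------------------------------------

#' Simulate two-haplotype SNV profiles
#'
#' At each divergent site two alleles segregate; in sample s reads derive
#' from haplotype 1 with probability \eqn{\theta_s}. Depth is Poisson
#' (left-truncated at 1), allele counts binomial, and sequencing error
#' \eqn{\epsilon} redistributes each read uniformly over the three other
#' bases. The expected per-site nucleotide diversity of the read pile at
#' error 0 and depth d is \eqn{2\theta(1-\theta)(1 - 1/d)}.
#'
#' @param thetas named numeric vector: haplotype-1 mixing proportion per
#'   sample, each in [0, 1].
#' @param n_sites number of divergent sites (default 1000).
#' @param depth_lambda Poisson mean depth (default 50).
#' @param error per-read error rate (default 0).
#' @param genome_len nominal genome length in bp (positions are sampled
#'   without replacement from it; default 1e6).
#' @param mag_id MAG identifier in the output (default "MAG1").
#' @param seed integer seed.
#' @return list with \code{sites} (site-count data.frame across samples)
#'   and \code{truth} (positions, the two alleles, thetas, model
#'   parameters).
#' @export
sim_snv_profiles <- function(thetas, n_sites = 1000, depth_lambda = 50,
                             error = 0, genome_len = 1e6,
                             mag_id = "MAG1", seed = 1) {
  stopifnot(all(thetas >= 0 & thetas <= 1), depth_lambda > 0)
  if (is.null(names(thetas))) stop("thetas must be named by sample")
  bases <- c("A", "C", "G", "T")
  truth <- with_seed(sub_seed(seed, "sites"), {
    pos <- sort(sample.int(genome_len, n_sites)) - 1L
    a1 <- sample(1:4, n_sites, replace = TRUE)
    a2 <- ((a1 - 1L + sample(1:3, n_sites, replace = TRUE)) %% 4L) + 1L
    data.frame(position = pos, allele1 = bases[a1], allele2 = bases[a2],
               stringsAsFactors = FALSE)
  })
  rows <- lapply(names(thetas), function(s) {
    with_seed(sub_seed(seed, paste0("sample_", s)), {
      th <- thetas[[s]]
      d <- pmax(1L, stats::rpois(n_sites, depth_lambda))
      k1 <- stats::rbinom(n_sites, d, th)
      cnt <- matrix(0L, n_sites, 4L)
      i1 <- match(truth$allele1, bases)
      i2 <- match(truth$allele2, bases)
      if (error > 0) {
        for (i in seq_len(n_sites)) {
          alleles <- c(rep(i1[i], k1[i]), rep(i2[i], d[i] - k1[i]))
          err <- stats::runif(d[i]) < error
          if (any(err))
            alleles[err] <- vapply(alleles[err], function(a)
              sample(setdiff(1:4, a), 1L), integer(1))
          cnt[i, ] <- tabulate(alleles, nbins = 4L)
        }
      } else {
        cnt[cbind(seq_len(n_sites), i1)] <- k1
        cnt[cbind(seq_len(n_sites), i2)] <-
          cnt[cbind(seq_len(n_sites), i2)] + (d - k1)
      }
      data.frame(mag_id = mag_id, sample_id = s,
                 position = truth$position,
                 nA = cnt[, 1L], nC = cnt[, 2L], nG = cnt[, 3L],
                 nT = cnt[, 4L], stringsAsFactors = FALSE)
    })
  })
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  list(sites = sites,
       truth = list(divergent = truth, thetas = thetas,
                    depth_lambda = depth_lambda, error = error,
                    genome_len = genome_len))
}

# ---- occurrence archetypes -------------------------------------------------

#' Simulate the niche-archetype occurrence battery
#'
#' Builds one occurrence profile per niche archetype, noise-free, with the
#' planted label as truth:
#' \itemize{
#'   \item persistent: five consecutive months in early 2017;
#'   \item seasonal: a short summer window present in both years;
#'   \item sporadic: a single 2017 month;
#'   \item other: occurrences in both years that no single 8-month
#'     calendar window of 2017 covers (the January-plus-September
#'     pattern);
#'   \item excluded_2018_only: present only in 2018.
#' }
#'
#' @param n_per_label profiles per archetype (default 1; additional copies
#'   are phase-shifted within the rules).
#' @param seed integer seed.
#' @return list with \code{profiles} (named list of logical month
#'   vectors), \code{abundance} (matching monthly RPKM values) and
#'   \code{truth} (data.frame mag_id, label).
#' @export
sim_occurrence <- function(n_per_label = 1, seed = 1) {
  axis <- study_month_axis()
  base <- list(
    persistent = c("2017-01", "2017-02", "2017-03", "2017-04", "2017-05"),
    seasonal = c("2017-06", "2017-07", "2018-06"),
    sporadic = c("2017-03"),
    other = c("2017-01", "2017-09", "2018-06"),
    excluded_2018_only = c("2018-05"))
  shift_months <- function(keys, by) {
    idx <- match(keys, axis) + by
    if (any(is.na(idx)) || any(idx < 1) || any(idx > length(axis)))
      return(NULL)
    axis[idx]
  }
  variants <- list(persistent = 1:3, seasonal = 1:2, sporadic = 1:6,
                   other = 0, excluded_2018_only = 1:3)
  profiles <- list(); truth <- list()
  for (label in names(base)) {
    for (rep_i in seq_len(n_per_label)) {
      months <- base[[label]]
      if (rep_i > 1) {
        sh <- with_seed(sub_seed(seed, paste(label, rep_i)),
                        sample(variants[[label]], 1L))
        shifted <- shift_months(base[[label]], sh)
        if (!is.null(shifted)) months <- shifted
      }
      mag <- sprintf("%s_%02d", label, rep_i)
      prof <- stats::setNames(rep(FALSE, length(axis)), axis)
      prof[months] <- TRUE
      profiles[[mag]] <- prof
      truth[[mag]] <- data.frame(mag_id = mag, label = label,
                                 stringsAsFactors = FALSE)
    }
  }
  abundance <- lapply(names(profiles), function(mag) {
    with_seed(sub_seed(seed, paste0("abund_", mag)), {
      a <- stats::setNames(rep(0, length(axis)), axis)
      a[profiles[[mag]]] <- stats::rlnorm(sum(profiles[[mag]]), 1, 0.5)
      a
    })
  })
  names(abundance) <- names(profiles)
  list(profiles = profiles, abundance = abundance,
       truth = do.call(rbind, truth))
}

# ---- clade fixture ---------------------------------------------------------

#' Simulate a clade with core-gene dropout and duplication
#'
#' Builds a guide tree with one well-defined clade (plus a long-branch
#' outgroup leaf) and an OG table where every clade member carries the
#' core OGs minus a fixed number of dropouts (\code{round(dropout *
#' n_core)} per genome, so the realised dropout rate equals the nominal
#' rate) and gains extra copies at the duplication rate. Expected
#' consistency is \code{1 - dropout}; with no duplication expected
#' redundancy is 0.
#'
#' @param n_genomes clade size (>= 4).
#' @param n_core number of core OGs (>= 10).
#' @param n_accessory number of rare accessory OGs (present in < half the
#'   genomes; default 8).
#' @param dropout per-genome core dropout rate in [0, 0.5).
#' @param dup_rate per-genome-per-OG duplication probability.
#' @param seed integer seed.
#' @return list with \code{tree} (\code{ape::phylo}), \code{og_table},
#'   \code{truth} (per-genome expected consistency and dropped OGs).
#' @export
sim_clade_fixture <- function(n_genomes = 12, n_core = 12, n_accessory = 8,
                              dropout = 0, dup_rate = 0, seed = 1) {
  stopifnot(n_genomes >= 4, n_core >= 10, dropout >= 0, dropout < 0.5)
  genomes <- sprintf("G%03d", seq_len(n_genomes))
  tips <- paste0(genomes, ":0.5", collapse = ",")
  nwk <- sprintf("(outgroup:3,(%s)clade:2)root;", tips)
  tree <- ape::read.tree(text = nwk)
  core <- sprintf("OG%03d", seq_len(n_core))
  acc <- if (n_accessory > 0)
    sprintf("ACC%03d", seq_len(n_accessory)) else character()
  k_drop <- round(dropout * n_core)
  rows <- list(); truth <- list()
  for (g in genomes) {
    with_seed(sub_seed(seed, g), {
      dropped <- if (k_drop > 0) sample(core, k_drop) else character()
      keep <- setdiff(core, dropped)
      copies <- 1L + stats::rbinom(length(keep), 1L, dup_rate)
      og <- data.frame(genome_id = g, og_id = keep, copy_count = copies,
                       stringsAsFactors = FALSE)
      if (length(acc)) {
        has <- stats::runif(length(acc)) < 0.25
        if (any(has))
          og <- rbind(og, data.frame(genome_id = g, og_id = acc[has],
                                     copy_count = 1L,
                                     stringsAsFactors = FALSE))
      }
      rows[[g]] <- og
      truth[[g]] <- data.frame(
        genome_id = g, n_dropped = k_drop,
        expected_consistency = 1 - k_drop / n_core,
        stringsAsFactors = FALSE)
    })
  }
  og_out <- rbind(do.call(rbind, rows),
                  data.frame(genome_id = "outgroup", og_id = "OGX01",
                             copy_count = 1L, stringsAsFactors = FALSE))
  rownames(og_out) <- NULL
  list(tree = tree, og_table = og_out, truth = do.call(rbind, truth))
}

# ---- genome pairs and seasonal fixtures ------------------------------------

#' Simulate a genome pair at a known nucleotide identity
#'
#' Draws a random genome and mutates a fixed fraction of positions
#' (uniformly placed, always to a different base), so the true identity of
#' the pair is exactly the requested value.
#'
#' @param len genome length in bp (default 1e5).
#' @param identity target identity in [0, 1] (default 0.97).
#' @param seed integer seed.
#' @return list with \code{a}, \code{b} (character sequences) and
#'   \code{n_mutated}.
#' @export
sim_genome_pair <- function(len = 1e5, identity = 0.97, seed = 1) {
  with_seed(sub_seed(seed, paste0("pair", len, identity)), {
    bases <- c("A", "C", "G", "T")
    a <- sample(bases, len, replace = TRUE)
    b <- a
    n_mut <- round((1 - identity) * len)
    if (n_mut > 0) {
      at <- sample.int(len, n_mut)
      b[at] <- vapply(b[at], function(x) sample(setdiff(bases, x), 1L),
                      character(1))
    }
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
         n_mutated = n_mut)
  })
}

#' Simulate a seasonal community over 24 months
#'
#' Every MAG occupies the same three calendar months in both years (a
#' phase drawn per MAG), so community composition recurs at 12-month lags
#' and is most dissimilar at 6-month lags.
#'
#' @param n_mags community size (default 40).
#' @param seed integer seed.
#' @return list with \code{presence} (logical MAG x month matrix over
#'   2017-01 .. 2018-12), \code{dates} (first of each month).
#' @export
sim_seasonal_community <- function(n_mags = 40, seed = 1) {
  months <- c(sprintf("2017-%02d", 1:12), sprintf("2018-%02d", 1:12))
  pres <- matrix(FALSE, n_mags, length(months),
                 dimnames = list(sprintf("MAG%03d", seq_len(n_mags)),
                                 months))
  for (i in seq_len(n_mags)) {
    phase <- with_seed(sub_seed(seed, paste0("mag", i)),
                       sample(0:11, 1L))
    season <- (phase + 0:2) %% 12
    pres[i, ((seq_along(months) - 1L) %% 12L) %in% season] <- TRUE
  }
  list(presence = pres,
       dates = as.Date(paste0(months, "-01")))
}

#' Simulate seasonally cycling allele frequencies for one MAG
#'
#' The haplotype-mixing proportion follows an annual sine wave, so samples
#' 12 months apart share their genetic structure while samples 6 months
#' apart are maximally differentiated.
#'
#' @param n_sites divergent sites (default 500).
#' @param n_months months, starting 2017-01 (default 24).
#' @param depth_lambda Poisson mean depth (default 100).
#' @param amplitude sine amplitude around 0.5 (default 0.45).
#' @param seed integer seed.
#' @return list with \code{sites} (site counts; sample ids are month
#'   keys), \code{dates}, \code{thetas}.
#' @export
sim_allele_cycling <- function(n_sites = 500, n_months = 24,
                               depth_lambda = 100, amplitude = 0.45,
                               seed = 1) {
  start <- as.Date("2017-01-01")
  dates <- seq(start, by = "month", length.out = n_months)
  keys <- format(dates, "%Y-%m")
  thetas <- stats::setNames(
    0.5 + amplitude * sin(2 * pi * (seq_len(n_months) - 1) / 12), keys)
  prof <- sim_snv_profiles(thetas, n_sites = n_sites,
                           depth_lambda = depth_lambda, seed = seed)
  list(sites = prof$sites, dates = stats::setNames(dates, keys),
       thetas = thetas, truth = prof$truth)
}
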