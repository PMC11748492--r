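#' Read a per-contig coverage depth table
#'
#' Parses the depth tables produced by coverage summarisers
#' (\code{jgi_summarize_bam_contig_depths} style: \code{contigName},
#' \code{contigLen}, \code{totalAvgDepth} followed by per-sample mean/variance
#' column pairs) or a plain dialect (\code{contig_id}, \code{contig_len},
#' one column per sample).
#'
#' @param path path to a tab-separated depth table.
#' @param dialect \code{"metabat"} (default) or \code{"plain"}.
#' @return data.frame with columns \code{contig_id}, \code{contig_len} and
#'   one numeric depth column per sample; variance columns (\code{*-var}) are
#'   preserved as extras. Attribute \code{"samples"} lists the depth column
#'   names.
#' @export
read_depth_table <- function(path, dialect = c("metabat", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("depth table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  id_col  <- if (dialect == "metabat") "contigName" else "contig_id"
  len_col <- if (dialect == "metabat") "contigLen" else "contig_len"
  for (col in c(id_col, len_col))
    if (!col %in% names(raw))
      stop("depth table format error: missing mandatory column '", col, "'")
  depth_cols <- setdiff(names(raw), c(id_col, len_col))
  depth_cols <- depth_cols[!grepl("-var$", depth_cols)]
  if (length(depth_cols) == 0L)
    stop("depth table format error: no depth column found")
  out <- data.frame(contig_id = raw[[id_col]],
                    contig_len = suppressWarnings(as.integer(
                      as.numeric(raw[[len_col]]))),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (anyNA(out$contig_len))
    stop("depth table format error: non-numeric contig length at line(s) ",
         paste(which(is.na(out$contig_len)) + 1L, collapse = ", "))
  if (any(out$contig_len <= 0))
    stop("depth table format error: non-positive contig length")
  for (col in c(depth_cols, grep("-var$", names(raw), value = TRUE))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v))
      stop("depth table format error: non-numeric depth in column '", col,
           "' at line(s) ", paste(which(is.na(v)) + 1L, collapse = ", "))
    out[[col]] <- v
  }
  if (any(as.matrix(out[depth_cols]) < 0))
    stop("depth table format error: negative depth value")
  attr(out, "samples") <- depth_cols
  out
}

#' Write a depth table
#'
#' Inverse of \code{\link{read_depth_table}}; round-trips the mandatory
#' columns losslessly.
#'
#' @param x data.frame as returned by \code{\link{read_depth_table}}.
#' @param path output path.
#' @param dialect \code{"metabat"} or \code{"plain"} (column naming only).
#' @return \code{path}, invisibly.
#' @export
write_depth_table <- function(x, path, dialect = c("metabat", "plain")) {
  dialect <- match.arg(dialect)
  out <- x
  if (dialect == "metabat")
    names(out)[match(c("contig_id", "contig_len"), names(out))] <-
      c("contigName", "contigLen")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read marker-gene hits
#'
#' Parses HMMER3 \code{--tblout} output or a pre-parsed TSV into an
#' aggregated hit table. Hits above the e-value cutoff are dropped (the drop
#' is recorded in the \code{"audit"} attribute, never silent) and multiple
#' hits of one marker on one contig are summed into \code{copy_count}.
#'
#' @param path input file. In tblout the target (column 1) is the contig and
#'   the query (column 3) the marker profile; the full-sequence e-value is
#'   column 5. The TSV dialect expects columns \code{contig_id},
#'   \code{marker_id}, \code{e_value} and optionally \code{copy_count}.
#' @param e_value_cutoff maximum e-value retained (default 1e-10).
#' @param dialect \code{"tblout"} or \code{"tsv"}.
#' @return data.frame with columns \code{contig_id}, \code{marker_id},
#'   \code{e_value} (best per pair) and \code{copy_count}; attribute
#'   \code{"audit"} logs the filtered rows.
#' @export
read_marker_hits <- function(path, e_value_cutoff = gv_config()$marker_evalue,
                             dialect = c("tblout", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("marker hit file not found: ", path)
  if (dialect == "tblout") {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(trimws(lines))
    hits <- data.frame(contig_id = character(), marker_id = character(),
                       e_value = numeric(), stringsAsFactors = FALSE)
    if (any(keep)) {
      fields <- strsplit(trimws(lines[keep]), "[ \t]+")
      bad <- which(lengths(fields) < 5L)
      if (length(bad))
        stop("unparseable tblout line(s): ",
             paste(which(keep)[bad], collapse = ", "))
      ev <- suppressWarnings(
        as.numeric(vapply(fields, `[[`, character(1), 5L)))
      if (anyNA(ev))
        stop("unparseable tblout e-value at line(s): ",
             paste(which(keep)[is.na(ev)], collapse = ", "))
      hits <- data.frame(
        contig_id = vapply(fields, `[[`, character(1), 1L),
        marker_id = vapply(fields, `[[`, character(1), 3L),
        e_value = ev, stringsAsFactors = FALSE)
    }
    hits$copy_count <- rep(1L, nrow(hits))
  } else {
    hits <- utils::read.delim(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    need <- c("contig_id", "marker_id", "e_value")
    miss <- setdiff(need, names(hits))
    if (length(miss))
      stop("marker TSV format error: missing column(s) ",
           paste(miss, collapse = ", "))
    if (is.null(hits$copy_count)) hits$copy_count <- 1L
  }
  dropped <- hits[hits$e_value > e_value_cutoff, , drop = FALSE]
  hits <- hits[hits$e_value <= e_value_cutoff, , drop = FALSE]
  if (nrow(hits)) {
    key <- paste(hits$contig_id, hits$marker_id, sep = "\r")
    agg <- data.frame(
      contig_id = hits$contig_id[!duplicated(key)],
      marker_id = hits$marker_id[!duplicated(key)],
      e_value = as.numeric(tapply(hits$e_value, key, min)[unique(key)]),
      copy_count = as.integer(tapply(hits$copy_count, key, sum)[unique(key)]),
      stringsAsFactors = FALSE)
    hits <- agg[order(agg$contig_id, agg$marker_id), , drop = FALSE]
    rownames(hits) <- NULL
  }
  audit <- if (nrow(dropped))
    gv_audit(paste(dropped$contig_id, dropped$marker_id, sep = ":"),
             "hit_dropped", "evalue_above_cutoff") else empty_audit()
  attr(hits, "audit") <- audit
  hits
}

#' Write an aggregated marker hit table (TSV dialect)
#'
#' @param x data.frame as returned by \code{\link{read_marker_hits}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_marker_hits <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-site nucleotide count table
#'
#' The substrate of all microdiversity computations: one row per
#' (MAG, sample, position) with A/C/G/T read counts. Positions are 0-based
#' within each MAG.
#'
#' @param path TSV with columns \code{mag_id}, \code{sample_id},
#'   \code{position}, \code{nA}, \code{nC}, \code{nG}, \code{nT}.
#' @return data.frame with those columns plus \code{depth} (= nA+nC+nG+nT)
#'   and \code{uncovered} (depth == 0).
#' @export
read_site_counts <- function(path) {
  if (!file.exists(path)) stop("site count table not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("mag_id", "sample_id", "position", "nA", "nC", "nG", "nT")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("site count format error: missing column(s) ",
         paste(miss, collapse = ", "))
  cnt <- as.matrix(x[, c("nA", "nC", "nG", "nT")])
  if (!is.numeric(cnt) || anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("site counts must be non-negative integers")
  x$depth <- as.integer(rowSums(cnt))
  x$uncovered <- x$depth == 0L
  x
}

#' Write a per-site nucleotide count table
#'
#' @param x data.frame with the mandatory site-count columns.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_site_counts <- function(x, path) {
  cols <- c("mag_id", "sample_id", "position", "nA", "nC", "nG", "nT")
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path CSV or TSV (sniffed from the extension; .csv = comma) with
#'   columns \code{sample_id}, \code{collection_date} (ISO date) and
#'   optionally \code{site_label} plus numeric environmental variables.
#' @return data.frame with a derived \code{month_key} (YYYY-MM) column;
#'   attribute \code{"env_vars"} names the environmental columns.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- utils::read.delim(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "collection_date")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sample table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id)) stop("sample ids must be unique")
  d <- as.Date(as.character(x$collection_date), format = "%Y-%m-%d")
  if (anyNA(d))
    stop("unparseable collection_date for sample(s): ",
         paste(x$sample_id[is.na(d)], collapse = ", "))
  x$collection_date <- d
  x$month_key <- format(d, "%Y-%m")
  env <- names(x)[vapply(x, is.numeric, logical(1))]
  attr(x, "env_vars") <- setdiff(env, c("sample_id"))
  x
}

#' Read a bin membership table
#'
#' @param path TSV with columns \code{bin_id}, \code{contig_id}.
#' @return data.frame with those two character columns.
#' @export
read_bin_membership <- function(path) {
  if (!file.exists(path)) stop("bin membership table not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("bin_id", "contig_id"), names(x))
  if (length(miss))
    stop("bin membership format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(x$contig_id))
    stop("a contig may belong to at most one bin")
  x
}

#' Read an orthologous-group membership table
#'
#' @param path TSV with columns \code{genome_id}, \code{og_id} and
#'   optionally \code{copy_count} (default 1).
#' @return data.frame with columns \code{genome_id}, \code{og_id},
#'   \code{copy_count}.
#' @export
read_og_table <- function(path) {
  if (!file.exists(path)) stop("OG table not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("genome_id", "og_id"), names(x))
  if (length(miss))
    stop("OG table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (is.null(x$copy_count)) x$copy_count <- 1L
  if (any(x$copy_count < 1)) stop("OG copy counts must be >= 1")
  x
}

#' Read a per-contig taxonomic tool verdict table
#'
#' @param path TSV with columns \code{contig_id}, \code{tool_name},
#'   \code{verdict} (one of \code{target_lineage}, \code{other},
#'   \code{none}).
#' @return validated data.frame.
#' @export
read_tool_verdicts <- function(path) {
  if (!file.exists(path)) stop("verdict table not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("contig_id", "tool_name", "verdict"), names(x))
  if (length(miss))
    stop("verdict table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(x$verdict), c("target_lineage", "other", "none"))
  if (length(bad))
    stop("unknown verdict value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(paste(x$contig_id, x$tool_name)))
    stop("at most one verdict per (contig, tool)")
  x
}
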