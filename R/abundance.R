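#' Construct a sample-by-genus read-count table
#'
#' @param counts Integer matrix, rows = samples, columns = genera, with
#'   dimnames.  Counts must be nonnegative whole numbers.
#' @param metadata Data frame with one row per sample and at least a
#'   `sample_id` column; typical columns are `rat_id`, `group`
#'   (single/multiple), `time_point`, `environment` (fecal/GMM/GMM_probiotic),
#'   `is_control` and optionally `known_enterotype`.
#' @return Object of class `count_table`.
#' @export
count_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_es("counts must carry sample and genus dimnames")
  if (anyDuplicated(rownames(counts)))
    stop_es("duplicate sample ids in count matrix")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_es("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  metadata <- as.data.frame(metadata)
  if (!"sample_id" %in% names(metadata))
    stop_es("metadata must contain a sample_id column")
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing))
    stop_es("metadata missing for samples: ", paste(missing, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, metadata = metadata), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "samples x", ncol(x$counts), "genera;",
      "total reads", sum(x$counts), "\n")
  invisible(x)
}

#' Read a count table and its sample metadata
#'
#' Accepts wide (first column = sample id, remaining columns = genera) or
#' long (`sample`, `genus`, `reads` columns) dialects, auto-detected from the
#' header; CSV or TSV by file extension.  Long input is aggregated by
#' summation over duplicate (sample, genus) rows.
#'
#' @param count_path Path to the count file.
#' @param metadata_path Path to a TSV/CSV metadata table with a `sample_id`
#'   column.
#' @return A `count_table`.
#' @export
read_counts <- function(count_path, metadata_path) {
  if (!file.exists(count_path)) stop_es("count file not found: ", count_path)
  if (!file.exists(metadata_path))
    stop_es("metadata file not found: ", metadata_path)
  df <- read_table_auto(count_path)
  lc <- tolower(names(df))
  if (all(c("sample", "genus", "reads") %in% lc)) {
    names(df) <- lc
    if (!is.numeric(df$reads) || any(is.na(df$reads)))
      stop_es("parse error: non-numeric read counts")
    if (any(df$reads < 0)) stop_es("parse error: negative read counts")
    tab <- stats::xtabs(reads ~ sample + genus, data = df)
    counts <- matrix(as.numeric(tab), nrow = nrow(tab),
                     dimnames = stats::setNames(dimnames(tab), NULL))
  } else {
    samples <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m) || any(is.na(m)))
      stop_es("parse error: non-numeric read counts")
    if (any(m < 0)) stop_es("parse error: negative read counts")
    rownames(m) <- samples
    counts <- m
  }
  meta <- read_table_auto(metadata_path)
  count_table(counts, meta)
}

#' Write a count table (wide TSV) plus metadata TSV
#'
#' Columns are emitted in deterministic (current) order.
#'
#' @param tbl A `count_table`.
#' @param count_path,metadata_path Output paths.
#' @return `count_path`, invisibly.
#' @export
write_counts <- function(tbl, count_path, metadata_path = NULL) {
  df <- data.frame(sample = rownames(tbl$counts),
                   as.data.frame(tbl$counts, check.names = FALSE),
                   check.names = FALSE)
  write_tsv_det(df, count_path)
  if (!is.null(metadata_path)) write_tsv_det(tbl$metadata, metadata_path)
  invisible(count_path)
}

#' Select the marker-taxon panel
#'
#' A genus enters the panel when its relative abundance reaches
#' `threshold_percent` in at least one dataset (sample).  Panel order is
#' deterministic: descending maximum abundance, ties broken lexicographically.
#'
#' @param tbl A `count_table`.
#' @param threshold_percent Abundance threshold in percent (default 0.01;
#'   0.1 is the stricter alternative some analyses prefer).
#' @return Object of class `marker_panel` with `genus_ids`,
#'   `threshold_percent` and `source_sets`.
#' @export
select_marker_panel <- function(tbl, threshold_percent = 0.01) {
  stopifnot(inherits(tbl, "count_table"))
  if (threshold_percent <= 0) stop_es("threshold_percent must be > 0")
  if (nrow(tbl$counts) == 0 || sum(tbl$counts) == 0)
    stop_es("empty table: cannot build a marker panel")
  tot <- rowSums(tbl$counts)
  pct <- sweep(tbl$counts, 1, pmax(tot, 1), "/") * 100
  max_pct <- apply(pct, 2, max)
  keep <- names(max_pct)[max_pct >= threshold_percent]
  keep <- keep[order(-max_pct[keep], keep)]
  if (!length(keep)) stop_es("empty panel: no genus reaches the threshold")
  structure(list(genus_ids = keep, threshold_percent = threshold_percent,
                 source_sets = rownames(tbl$counts)),
            class = "marker_panel")
}

#' Percentage matrix over a marker panel
#'
#' Restricts counts to the panel, applies the outlier mask (masked cells are
#' excluded from both numerator and denominator) and converts to percentages.
#' With `pseudocount = 1`, one read is added to every zero-count panel genus
#' before normalization so downstream fold-change ratios stay finite; with
#' `pseudocount = 0` raw proportions are returned (clustering context).
#'
#' @param tbl A `count_table`.
#' @param panel A `marker_panel`, a character vector of genus ids, or `NULL`
#'   for all genera.
#' @param pseudocount 0 or 1.
#' @param mask Optional data frame with columns `sample` and `genus` listing
#'   cells to ignore.
#' @return Object of class `abundance_matrix`: list with `percent`
#'   (sample x genus matrix, unmasked entries of each row summing to 100),
#'   `mask`, `pseudocount`.
#' @export
percentages <- function(tbl, panel = NULL, pseudocount = 0, mask = NULL) {
  stopifnot(inherits(tbl, "count_table"))
  if (!pseudocount %in% c(0, 1)) stop_es("pseudocount must be 0 or 1")
  genus <- if (is.null(panel)) colnames(tbl$counts)
           else if (inherits(panel, "marker_panel")) panel$genus_ids
           else as.character(panel)
  if (!length(genus)) stop_es("panel is empty")
  missing <- setdiff(genus, colnames(tbl$counts))
  if (length(missing))
    stop_es("panel genera absent from table: ", paste(missing, collapse = ", "))
  m <- tbl$counts[, genus, drop = FALSE]
  storage.mode(m) <- "double"
  if (!is.null(mask) && nrow(mask)) {
    mask <- as.data.frame(mask)
    bad_s <- setdiff(mask$sample, rownames(m))
    if (length(bad_s)) stop_es("mask references unknown sample: ",
                               paste(bad_s, collapse = ", "))
    keep <- mask$genus %in% genus
    for (i in which(keep)) m[mask$sample[[i]], mask$genus[[i]]] <- NA
  } else {
    mask <- data.frame(sample = character(0), genus = character(0))
  }
  if (pseudocount == 1) m[!is.na(m) & m == 0] <- 1
  tot <- rowSums(m, na.rm = TRUE)
  degenerate <- tot == 0
  if (any(degenerate))
    stop_es("degenerate sample(s) with zero unmasked reads: ",
            paste(rownames(m)[degenerate], collapse = ", "))
  pct <- sweep(m, 1, tot, "/") * 100
  structure(list(percent = pct, mask = mask, pseudocount = pseudocount,
                 genus_ids = genus, sample_ids = rownames(pct)),
            class = "abundance_matrix")
}

#' Mask hand-flagged outlier cells and renormalize
#'
#' Convenience wrapper around [percentages()] for the audit workflow of
#' ignoring a contaminating genus in specific libraries: masked cells drop
#' out of the denominator so the remaining genera are renormalized to 100%.
#'
#' @inheritParams percentages
#' @param mask_list Data frame with columns `sample`, `genus`.
#' @return An `abundance_matrix`.
#' @export
mask_outliers <- function(tbl, mask_list, panel = NULL, pseudocount = 0) {
  percentages(tbl, panel = panel, pseudocount = pseudocount, mask = mask_list)
}

#' Advisory outlier detector
#'
#' Flags any (sample, genus) cell whose percentage exceeds `factor` times the
#' genus's 95th percentile across samples.  Never masks automatically; the
#' result may be reviewed and passed to [mask_outliers()].
#'
#' @param ab An `abundance_matrix`.
#' @param factor Multiplier on the per-genus 95th percentile.
#' @return Data frame with columns `sample`, `genus`, `percent`, `q95`.
#' @export
flag_outliers <- function(ab, factor = 10) {
  stopifnot(inherits(ab, "abundance_matrix"))
  p <- ab$percent
  q95 <- apply(p, 2, stats::quantile, probs = 0.95, na.rm = TRUE)
  hits <- which(sweep(p, 2, factor * pmax(q95, .Machine$double.eps), ">"),
                arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(sample = character(0), genus = character(0),
                      percent = numeric(0), q95 = numeric(0)))
  data.frame(sample = rownames(p)[hits[, 1]],
             genus = colnames(p)[hits[, 2]],
             percent = p[hits], q95 = q95[hits[, 2]], row.names = NULL)
}

#' Per-sample phylum percentages and the B/F ratio
#'
#' Aggregates an abundance matrix to phylum level (genera missing from the
#' map fall into `"other"`) and reports the Bacteroidota/Bacillota percentage
#' ratio, the discriminator separating the two enterotypes.
#'
#' @param ab An `abundance_matrix`.
#' @param phylum_of Named character vector, genus -> phylum.
#' @return Data frame with `sample_id`, one column per phylum (percent,
#'   summing to 100 per row) and `bf_ratio` (`Inf` when Bacillota is absent).
#' @export
phylum_summary <- function(ab, phylum_of) {
  stopifnot(inherits(ab, "abundance_matrix"))
  ph <- phylum_of[ab$genus_ids]
  ph[is.na(ph)] <- "other"
  phyla <- unique(ph)
  agg <- sapply(phyla, function(p)
    rowSums(ab$percent[, ph == p, drop = FALSE], na.rm = TRUE))
  agg <- matrix(agg, nrow = nrow(ab$percent),
                dimnames = list(rownames(ab$percent), phyla))
  bact <- if ("Bacteroidota" %in% phyla) agg[, "Bacteroidota"] else 0
  firm <- if ("Bacillota" %in% phyla) agg[, "Bacillota"] else 0
  bf <- ifelse(firm == 0, Inf, bact / firm)
  out <- data.frame(sample_id = rownames(ab$percent),
                    as.data.frame(agg, check.names = FALSE),
                    bf_ratio = bf, check.names = FALSE)
  rownames(out) <- NULL
  out
}
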