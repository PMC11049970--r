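#' Build control-experimental sample pairs
#'
#' Three pairing schemes mirror the study designs:
#' * `dosing` - each treated fecal sample taken while dosing is ongoing is
#'   paired with its rat's 0h control (24h after every administered dose);
#' * `recovery` - post-treatment fecal samples are paired with the same 0h
#'   control, so one control serves several time points;
#' * `in_vitro` - an ex vivo culture (`GMM`) is paired with the parallel
#'   probiotic-supplemented culture (`GMM_probiotic`) of the same origin and
#'   duration.
#'
#' @param metadata Sample metadata data frame (columns `sample_id`,
#'   `rat_id`, `group`, `time_point`, `environment`, `is_control`, and
#'   optionally `known_enterotype`).
#' @param scheme One of `"dosing"`, `"recovery"`, `"in_vitro"`.
#' @param exclude Optional character vector of `"control:experimental"` pair
#'   keys to drop (hand-curated exclusions).
#' @return Data frame with columns `control`, `experimental`, `group_label`,
#'   `rat_id`, `enterotype` (NA when unknown).
#' @export
build_pairs <- function(metadata, scheme = c("dosing", "recovery", "in_vitro"),
                        exclude = NULL) {
  scheme <- match.arg(scheme)
  md <- as.data.frame(metadata)
  etype <- if ("known_enterotype" %in% names(md)) md$known_enterotype
           else rep(NA_character_, nrow(md))
  names(etype) <- md$sample_id

  if (scheme %in% c("dosing", "recovery")) {
    fec <- md[md$environment == "fecal", , drop = FALSE]
    ctrl <- fec[fec$is_control, , drop = FALSE]
    ctrl_of <- stats::setNames(ctrl$sample_id, ctrl$rat_id)
    trt <- fec[!fec$is_control, , drop = FALSE]
    miss <- setdiff(unique(trt$rat_id), names(ctrl_of))
    if (length(miss))
      stop_es("pairing error: rat(s) lacking a 0h control: ",
              paste(miss, collapse = ", "))
    t_day <- time_point_days(trt$time_point)
    last_dose <- ifelse(trt$group == "multiple", 2, 0)
    in_dosing <- t_day <= last_dose + 1
    keep <- if (scheme == "dosing") in_dosing else !in_dosing
    trt <- trt[keep, , drop = FALSE]
    if (!nrow(trt))
      return(data.frame(control = character(0), experimental = character(0),
                        group_label = character(0), rat_id = character(0),
                        enterotype = character(0)))
    dose_idx <- pmin(ceiling(time_point_days(trt$time_point)), 3)
    group_label <- if (scheme == "dosing")
      paste0("dose", dose_idx, "_", trt$time_point)
    else paste0("recovery_", trt$time_point)
    out <- data.frame(control = unname(ctrl_of[trt$rat_id]),
                      experimental = trt$sample_id,
                      group_label = group_label,
                      rat_id = trt$rat_id,
                      enterotype = unname(etype[trt$sample_id]))
  } else {
    gm <- md[md$environment == "GMM", , drop = FALSE]
    pr <- md[md$environment == "GMM_probiotic", , drop = FALSE]
    key <- function(x) paste(x$rat_id, x$time_point)
    m <- match(key(gm), key(pr))
    ok <- !is.na(m)
    out <- data.frame(control = gm$sample_id[ok],
                      experimental = pr$sample_id[m[ok]],
                      group_label = paste0("invitro_", gm$time_point[ok]),
                      rat_id = gm$rat_id[ok],
                      enterotype = unname(etype[gm$sample_id[ok]]))
  }
  if (!is.null(exclude) && length(exclude)) {
    keys <- paste0(out$control, ":", out$experimental)
    out <- out[!keys %in% exclude, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Fold-change ratios for paired samples
#'
#' `fcr = experimental% / control%` per genus per pair, computed on a
#' pseudocounted abundance matrix so the ratio is always finite and positive.
#'
#' @param ab An `abundance_matrix` built with `pseudocount = 1`.
#' @param pairs Pair data frame from [build_pairs()].
#' @return Long data frame: `genus`, `control`, `experimental`,
#'   `group_label`, `con_pct`, `exp_pct`, `fcr`.
#' @export
compute_fcr <- function(ab, pairs) {
  stopifnot(inherits(ab, "abundance_matrix"))
  if (ab$pseudocount != 1)
    stop_es("compute_fcr requires an abundance matrix with pseudocount = 1")
  miss <- setdiff(unique(c(pairs$control, pairs$experimental)),
                  rownames(ab$percent))
  if (length(miss))
    stop_es("pair member(s) missing from abundance matrix: ",
            paste(miss, collapse = ", "))
  genus <- colnames(ab$percent)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    con <- ab$percent[pairs$control[[i]], ]
    exp_ <- ab$percent[pairs$experimental[[i]], ]
    out[[i]] <- data.frame(genus = genus,
                           control = pairs$control[[i]],
                           experimental = pairs$experimental[[i]],
                           group_label = pairs$group_label[[i]],
                           con_pct = unname(con), exp_pct = unname(exp_),
                           fcr = unname(exp_ / con))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inclusion filter for FCR records
#'
#' A pair qualifies for a genus when the percentage on the side of the
#' change reaches `min_percent`: for increased abundance (`fcr >= 1`) the
#' experimental percentage, for suppression (`fcr < 1`) the control
#' percentage.  A genus is retained within a group when at least `min_pairs`
#' pairs qualify.
#'
#' @param records FCR records from [compute_fcr()].
#' @param min_percent Percentage threshold (default 0.01).
#' @param min_pairs Minimum qualifying pairs per genus and group (default 3).
#' @return The qualifying records (rows of `records` with a `qualifies`
#'   column), restricted to retained genus-group combinations.
#' @export
apply_inclusion_filter <- function(records, min_percent = 0.01,
                                   min_pairs = 3) {
  q <- (records$fcr >= 1 & records$exp_pct >= min_percent) |
       (records$fcr < 1 & records$con_pct >= min_percent)
  rec <- records[q, , drop = FALSE]
  if (!nrow(rec)) return(rec)
  key <- paste(rec$genus, rec$group_label, sep = "\r")
  n_by <- table(key)
  rec <- rec[n_by[key] >= min_pairs, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' One-sample Z-statistic against FCR = 1
#'
#' Averages the qualifying fold-change ratios, estimates their standard
#' deviation and tests the mean against the null FCR = 1.  The default
#' denominator is the standard error `sd/sqrt(n)`; `denominator = "sd"`
#' reproduces the population-spread variant.  The one-sided tail p-value is
#' computed as `pnorm(|z|, lower.tail = FALSE)`, which stays accurate far
#' beyond |z| = 8; for still larger statistics the log-scale tail
#' (`log.p = TRUE`) is carried alongside, so `neg_log10_p` remains finite
#' even where the p-value itself underflows double precision.
#'
#' @param fcrs Numeric vector of qualifying fold-change ratios (length >= 3).
#' @param denominator `"se"` (default) or `"sd"`.
#' @return List with `n`, `mean_fcr`, `sd_fcr`, `z`, `p`, `neg_log10_p`,
#'   `direction` (`"stimulated"`/`"suppressed"`), `degenerate` (TRUE when
#'   sd = 0, in which case `p` is `NA`).
#' @export
z_statistic <- function(fcrs, denominator = c("se", "sd")) {
  denominator <- match.arg(denominator)
  n <- length(fcrs)
  if (n < 3) stop_es("z_statistic needs at least 3 qualifying pairs")
  m <- mean(fcrs)
  s <- stats::sd(fcrs)
  direction <- if (m >= 1) "stimulated" else "suppressed"
  if (s == 0) {
    return(list(n = n, mean_fcr = m, sd_fcr = 0, z = NA_real_, p = NA_real_,
                neg_log10_p = NA_real_, direction = direction,
                degenerate = TRUE))
  }
  den <- if (denominator == "se") s / sqrt(n) else s
  z <- (m - 1) / den
  log_p <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  list(n = n, mean_fcr = m, sd_fcr = s, z = z, p = exp(log_p),
       neg_log10_p = -log_p / log(10), direction = direction,
       degenerate = FALSE)
}

#' Per-genus differential response table
#'
#' Applies [z_statistic()] to every genus-group combination of the filtered
#' FCR records.
#'
#' @param records Filtered records from [apply_inclusion_filter()].
#' @param denominator Passed to [z_statistic()].
#' @return Data frame (class `differential_result`) with one row per genus
#'   and group: `genus`, `group_label`, `n`, `mean_fcr`, `sd_fcr`, `z`, `p`,
#'   `direction`, `degenerate`.
#' @export
differential_test <- function(records, denominator = "se") {
  if (!nrow(records))
    return(structure(data.frame(genus = character(0),
                                group_label = character(0), n = integer(0),
                                mean_fcr = numeric(0), sd_fcr = numeric(0),
                                z = numeric(0), p = numeric(0),
                                neg_log10_p = numeric(0),
                                direction = character(0),
                                degenerate = logical(0)),
                     class = c("differential_result", "data.frame")))
  split_key <- interaction(records$genus, records$group_label, drop = TRUE,
                           sep = "\r")
  rows <- lapply(split(records, split_key), function(g) {
    zs <- z_statistic(g$fcr, denominator = denominator)
    data.frame(genus = g$genus[[1]], group_label = g$group_label[[1]],
               n = zs$n, mean_fcr = zs$mean_fcr, sd_fcr = zs$sd_fcr,
               z = zs$z, p = zs$p, neg_log10_p = zs$neg_log10_p,
               direction = zs$direction, degenerate = zs$degenerate)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group_label, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Volcano export table
#'
#' @param results A `differential_result`.
#' @return Data frame with `genus`, `group_label`, `log2_mean_fcr`,
#'   `neg_log10_p`, `direction` and `tier` (`"strong"` at p <= 0.001,
#'   `"significant"` at p < 0.05, else `"ns"`).
#' @export
volcano_table <- function(results) {
  if (!nrow(results)) stop_es("no differential results to export")
  tier <- ifelse(is.na(results$p), "ns",
          ifelse(results$p <= 0.001, "strong",
          ifelse(results$p < 0.05, "significant", "ns")))
  nlp <- if ("neg_log10_p" %in% names(results)) results$neg_log10_p
         else -log10(results$p)
  out <- data.frame(genus = results$genus, group_label = results$group_label,
                    log2_mean_fcr = log2(results$mean_fcr),
                    neg_log10_p = nlp,
                    direction = results$direction, tier = tier)
  # advisory Benjamini-Hochberg column; headline tiers stay on raw p
  out$p_bh <- stats::p.adjust(results$p, method = "BH")
  out
}

#' Collapse a differential result to one row per genus
#'
#' Keeps, for each genus, the row with the smallest p-value across groups
#' (the strongest response over the time course).
#'
#' @param results A `differential_result`.
#' @return A `differential_result` with unique genera.
#' @export
collapse_by_genus <- function(results) {
  if (!nrow(results)) return(results)
  p <- ifelse(is.na(results$p), Inf, results$p)
  ord <- order(results$genus, p)
  res <- results[ord, , drop = FALSE]
  out <- res[!duplicated(res$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-context concordance labels
#'
#' Compares two per-genus differential results (e.g. in vitro vs in vivo):
#' a genus significant in both contexts at `alpha` gets `"similar"` when the
#' directions agree and `"opposite"` when they are discordant; everything
#' else is `"none"`.
#'
#' @param results_a,results_b Per-genus `differential_result` tables (use
#'   [collapse_by_genus()] if needed).
#' @param alpha Significance level (default 0.05).
#' @return Data frame with `genus`, `direction_a`, `p_a`, `direction_b`,
#'   `p_b`, `label`.
#' @export
concordance <- function(results_a, results_b, alpha = 0.05) {
  a <- collapse_by_genus(results_a)
  b <- collapse_by_genus(results_b)
  genus <- intersect(a$genus, b$genus)
  ia <- match(genus, a$genus); ib <- match(genus, b$genus)
  sig_a <- !is.na(a$p[ia]) & a$p[ia] < alpha
  sig_b <- !is.na(b$p[ib]) & b$p[ib] < alpha
  same <- a$direction[ia] == b$direction[ib]
  label <- ifelse(sig_a & sig_b & same, "similar",
           ifelse(sig_a & sig_b & !same, "opposite", "none"))
  data.frame(genus = genus,
             direction_a = a$direction[ia], p_a = a$p[ia],
             direction_b = b$direction[ib], p_b = b$p[ib],
             label = label)
}

#' Set overlap against the chance expectation
#'
#' Observed intersection of two genus sets versus the expectation
#' `|A| * |B| / |U|` under random draws from the monitored universe, with an
#' advisory hypergeometric enrichment p-value.
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Character vector of monitored genera.
#' @return List with `n_a`, `n_b`, `n_universe`, `observed`, `expected`,
#'   `p_enrichment`.
#' @export
overlap_summary <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_es("domain error: empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop_es("sets must be subsets of the universe")
  obs <- length(intersect(set_a, set_b))
  expd <- length(set_a) * length(set_b) / length(universe)
  p <- stats::phyper(obs - 1, length(set_a),
                     length(universe) - length(set_a), length(set_b),
                     lower.tail = FALSE)
  list(n_a = length(set_a), n_b = length(set_b),
       n_universe = length(universe), observed = obs, expected = expd,
       p_enrichment = p)
}
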