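#' Shannon diversity of one composition
#'
#' `H' = -sum p log_base p` over the positive entries of a proportion (or
#' percentage) vector.
#'
#' @param p Nonnegative numeric vector; normalized internally.
#' @param base Logarithm base, 2 (bits, default) or `exp(1)`.
#' @return Numeric H'.
#' @export
shannon_index <- function(p, base = 2) {
  if (any(p < 0)) stop_es("domain error: negative abundances")
  s <- sum(p)
  if (s == 0) stop_es("domain error: all-zero composition")
  q <- p[p > 0] / s
  -sum(q * log(q, base = base))
}

#' Per-sample diversity table
#'
#' @param tbl A `count_table`.
#' @param base Logarithm base for H'.
#' @return Data frame with `sample_id`, `shannon` and `n_taxa` (genera with
#'   at least one read).
#' @export
diversity_table <- function(tbl, base = 2) {
  stopifnot(inherits(tbl, "count_table"))
  data.frame(sample_id = rownames(tbl$counts),
             shannon = apply(tbl$counts, 1, shannon_index, base = base),
             n_taxa = rowSums(tbl$counts > 0),
             row.names = NULL)
}

#' Two-group comparison with a normality gate
#'
#' Shapiro-Wilk normality is checked on each group at the 0.05 level; when
#' both pass, a pooled-variance Student's t-test is used, otherwise the
#' Mann-Whitney rank-sum test.  Constant groups are flagged as degenerate
#' and routed to the rank-sum branch.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @return List with `method` (`"t"`/`"rank-sum"`), `statistic`, `p_value`,
#'   `normality_p` (length-2), `degenerate`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop_es("each group needs at least 3 values")
  degenerate <- stats::sd(values_a) == 0 || stats::sd(values_b) == 0
  norm_p <- vapply(list(values_a, values_b), function(v) {
    if (stats::sd(v) == 0) return(0)  # constant: fails normality by fiat
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (all(norm_p > 0.05)) {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    method <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              exact = FALSE))
    method <- "rank-sum"
  }
  list(method = method, statistic = unname(ht$statistic),
       p_value = ht$p.value, normality_p = norm_p, degenerate = degenerate)
}

#' Candidate pool for representative-taxon selection
#'
#' Genera showing at least a `min_fold` change (in either direction) with
#' `p < alpha` at one or more time points.  With
#' `require_all_groups = TRUE` a candidate must additionally have passed the
#' inclusion filters (i.e. have a result row) in every compared group.
#'
#' @param results A `differential_result` spanning the time points.
#' @param min_fold Fold-change bound (default 2; suppression bound is its
#'   reciprocal).
#' @param alpha Significance level (default 0.05).
#' @param require_all_groups Require presence in all groups (default TRUE).
#' @return Character vector of candidate genera.
#' @export
candidate_pool <- function(results, min_fold = 2, alpha = 0.05,
                           require_all_groups = TRUE) {
  if (!nrow(results)) return(character(0))
  hit <- (results$mean_fcr >= min_fold |
            results$mean_fcr <= 1 / min_fold) &
         !is.na(results$p) & results$p < alpha
  cand <- unique(results$genus[hit])
  if (require_all_groups) {
    groups <- unique(results$group_label)
    n_groups <- vapply(cand, function(g)
      length(unique(results$group_label[results$genus == g])), numeric(1))
    cand <- cand[n_groups == length(groups)]
  }
  sort(cand)
}

#' Stepwise selection of representative taxa
#'
#' Cycles through the composition profiles `rounds` times; at each step the
#' not-yet-selected pool genus with the highest percentage in the current
#' profile is taken (ties go to the lexicographically smaller genus).  The
#' full selection has exactly `rounds * length(profile order)` taxa.
#'
#' @param pool Character vector of candidate genera.
#' @param profiles Percentage matrix, rows = profiles in selection order
#'   (e.g. alternating E1/E2 samples along the time course), columns
#'   including all pool genera.
#' @param rounds Number of full cycles (default 5).
#' @return Object of class `pie_selection`: `taxa` (ordered), `picks`
#'   (data frame round/profile/genus/percent), `profiles` (the percent
#'   submatrix over selected taxa), `totals`, `removed_dominants`.
#' @export
select_representatives <- function(pool, profiles, rounds = 5) {
  profiles <- as.matrix(profiles)
  pool <- intersect(pool, colnames(profiles))
  need <- rounds * nrow(profiles)
  selected <- character(0)
  picks <- vector("list", need)
  step <- 0L
  short <- FALSE
  for (r in seq_len(rounds)) {
    for (i in seq_len(nrow(profiles))) {
      avail <- setdiff(pool, selected)
      if (!length(avail)) { short <- TRUE; break }
      v <- profiles[i, avail]
      best <- avail[order(-v, avail)][[1]]
      selected <- c(selected, best)
      step <- step + 1L
      picks[[step]] <- data.frame(round = r,
                                  profile = rownames(profiles)[[i]],
                                  genus = best,
                                  percent = unname(profiles[i, best]))
    }
    if (short) break
  }
  picks <- do.call(rbind, picks[seq_len(step)])
  sel <- structure(list(taxa = selected,
                        picks = picks,
                        profiles = profiles[, selected, drop = FALSE],
                        totals = rowSums(profiles[, selected, drop = FALSE]),
                        removed_dominants = character(0)),
                   class = "pie_selection")
  if (short) {
    cond <- structure(
      class = c("short_selection_error", "error", "condition"),
      list(message = paste0("short selection: pool exhausted after ",
                            length(selected), " of ", need, " taxa"),
           call = NULL, partial = sel))
    stop(cond)
  }
  sel
}

#' Remove the dominant taxon of each control profile
#'
#' Post hoc removal of the per-control-profile dominant among the selected
#' taxa (one per listed profile) to improve resolution for the remaining
#' genera; totals are recomputed.  Profiles sharing the same dominant cause
#' only a single removal.
#'
#' @param sel A `pie_selection`.
#' @param control_profiles Row names of the control profiles.
#' @return The reduced `pie_selection`.
#' @export
remove_dominants <- function(sel, control_profiles) {
  stopifnot(inherits(sel, "pie_selection"))
  if (!length(sel$taxa)) stop_es("empty selection")
  drop <- character(0)
  for (pr in control_profiles) {
    v <- sel$profiles[pr, sel$taxa]
    ord <- sel$taxa[order(-v, sel$taxa)]
    drop <- union(drop, ord[[1]])
  }
  keep <- setdiff(sel$taxa, drop)
  sel$taxa <- keep
  sel$profiles <- sel$profiles[, keep, drop = FALSE]
  sel$totals <- rowSums(sel$profiles)
  sel$removed_dominants <- union(sel$removed_dominants, drop)
  sel$picks <- sel$picks[sel$picks$genus %in% keep, , drop = FALSE]
  sel
}

#' Normalizing sector per profile
#'
#' The padding value `N(profile) = max(total) - total(profile)` that
#' equalizes the summed selected-taxa percentage across composition charts;
#' all padded totals are exactly equal and N is never negative.
#'
#' @param sel A `pie_selection`.
#' @return Named numeric vector of N values.
#' @export
normalizing_sector <- function(sel) {
  stopifnot(inherits(sel, "pie_selection"))
  max(sel$totals) - sel$totals
}
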