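#' Default end-to-end run configuration
#'
#' Thresholds follow the study conventions: marker panel at 0.01% abundance
#' (0.1% is the stricter alternative), silhouette vote threshold 0.1,
#' volcano significance tiers 0.001/0.05, inclusion filter at 0.01% with at
#' least 3 qualifying pairs, 2-fold candidate bound.  Without input paths the
#' pipeline simulates a cohort (21 rats, two enterotypes, planted effects).
#'
#' @param seed Integer seed driving simulation and every downstream stage.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    input = NULL,  # list(counts=, metadata=, phylum_map=) to analyze files
    simulation = list(n_genera = 220, depth = 30000,
                      rat_overdispersion = 200, effects = "default"),
    thresholds = list(marker_percent = 0.01, silhouette = 0.1,
                      p_strong = 0.001, p_sig = 0.05,
                      min_pairs = 3, min_percent = 0.01, min_fold = 2),
    selection = list(rounds = 5, n_control_profiles = 2)
  )
}

validate_config <- function(config) {
  th <- config$thresholds
  if (any(unlist(th) <= 0)) stop_es("config error: thresholds must be positive")
  if (th$p_strong >= 1 || th$p_sig >= 1)
    stop_es("config error: p tiers must lie in (0, 1)")
  if (!is.null(config$input)) {
    for (f in unlist(config$input))
      if (!file.exists(f)) stop_es("config error: input file not found: ", f)
  }
  invisible(config)
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return Configuration list merged over [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_lists(cfg, user)
}

# Split samples into per-time-point abundance matrices; controls are "con".
split_by_time_point <- function(ab, metadata) {
  set_of <- ifelse(metadata$is_control, "con", metadata$time_point)
  names(set_of) <- metadata$sample_id
  sets <- unique(set_of)
  # keep chronological order: con first, then by day
  rest <- setdiff(sets, "con")
  sets <- c("con", rest[order(time_point_days(rest))])
  out <- lapply(sets, function(s) {
    ids <- names(set_of)[set_of == s]
    ab$percent[ids, , drop = FALSE]
  })
  names(out) <- sets
  out
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: acquire counts (simulate or read), build the
#' marker panel, type the control samples (JSD -> PAM k=2, larger cluster
#' named E1; CH scan reported), score the silhouette stability grid over all
#' pooled time-point combinations, call every sample's enterotype by the
#' vote rule, tabulate per-rat shifts, run the paired FCR analysis per
#' enterotype (dosing and recovery schemes), compute diversity, and perform
#' the representative-taxon selection with normalizing sector.  All
#' randomness flows from `config$seed`; identical configurations reproduce
#' identical outputs.
#'
#' @param config Configuration list ([default_config()]) or a YAML path.
#' @param out_dir Optional directory for TSV/JSON artifacts.
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  th <- config$thresholds
  seed <- config$seed
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  # --- stage: data ---------------------------------------------------------
  if (!is.null(config$input)) {
    tbl <- read_counts(config$input$counts, config$input$metadata)
    ph <- read_table_auto(config$input$phylum_map)
    phylum_of <- stats::setNames(ph[[2]], ph[[1]])
    truth <- NULL
  } else {
    sim <- config$simulation
    tpl <- build_template(n_genera = sim$n_genera, seed = seed)
    eff <- if (identical(sim$effects, "default")) default_effect_model(tpl)
           else null_effect_model()
    des <- synthetic_design(depth = sim$depth,
                            rat_overdispersion = sim$rat_overdispersion,
                            seed = seed)
    cohort <- simulate_cohort(des, tpl, eff)
    tbl <- cohort$table
    truth <- cohort$truth
    phylum_of <- tpl$phylum_of
  }
  md <- tbl$metadata

  # --- stage: panel and percentages ---------------------------------------
  panel <- select_marker_panel(tbl, th$marker_percent)
  ab0 <- percentages(tbl, panel, pseudocount = 0)
  ab1 <- percentages(tbl, panel, pseudocount = 1)
  phyla <- phylum_summary(ab0, phylum_of)

  # --- stage: reference enterotyping of controls --------------------------
  ctrl_ids <- md$sample_id[md$is_control & md$environment == "fecal"]
  d_ctrl <- jsd_distance(ab0$percent[ctrl_ids, , drop = FALSE])
  scan <- ch_scan(d_ctrl, 2:min(5, length(ctrl_ids) - 1))
  part <- pam_partition(d_ctrl, 2)
  sizes <- table(part$labels)
  big <- as.integer(names(sizes)[which.max(sizes)])
  reference <- stats::setNames(
    ifelse(part$labels == big, "E1", "E2"), names(part$labels))
  rat_of <- stats::setNames(md$rat_id, md$sample_id)
  rat_etype <- stats::setNames(reference[ctrl_ids], rat_of[ctrl_ids])

  # --- stage: stability grid and calls ------------------------------------
  ab_by_set <- split_by_time_point(ab0, md)
  grid <- stability_grid(ab_by_set, reference, rat_of = rat_of,
                         k = 2)
  calls <- call_all_enterotypes(grid, threshold = th$silhouette)
  shifts <- shift_table(calls, md)

  # --- stage: differential response ---------------------------------------
  differential <- list()
  for (e in sort(unique(rat_etype))) {
    rats_e <- names(rat_etype)[rat_etype == e]
    md_e <- md[md$rat_id %in% rats_e, , drop = FALSE]
    res_e <- list()
    for (scheme in c("dosing", "recovery")) {
      pairs <- build_pairs(md_e, scheme)
      if (!nrow(pairs)) next
      rec <- compute_fcr(ab1, pairs)
      rec <- apply_inclusion_filter(rec, th$min_percent, th$min_pairs)
      res_e[[scheme]] <- differential_test(rec)
    }
    differential[[e]] <- do.call(rbind, res_e)
    if (!is.null(differential[[e]])) rownames(differential[[e]]) <- NULL
  }

  # --- stage: diversity ----------------------------------------------------
  div <- diversity_table(tbl)
  div_compare <- NULL
  h_ctrl <- split(div$shannon[match(ctrl_ids, div$sample_id)],
                  reference[ctrl_ids])
  if (length(h_ctrl) == 2 && all(lengths(h_ctrl) >= 3))
    div_compare <- compare_groups(h_ctrl[[1]], h_ctrl[[2]])

  # --- stage: representative selection ------------------------------------
  sel <- NULL; sector <- NULL
  sel_cfg <- config$selection
  prof_ids <- selection_profiles(md, rat_etype)
  if (!is.null(prof_ids)) {
    profiles <- ab0$percent[prof_ids, , drop = FALSE]
    pool <- candidate_pool(do.call(rbind, differential),
                           min_fold = th$min_fold, alpha = th$p_sig,
                           require_all_groups = FALSE)
    need <- sel_cfg$rounds * nrow(profiles)
    if (length(pool) < need) {
      note(paste0("candidate pool (", length(pool), ") smaller than ", need,
                  "; falling back to all panel genera for selection"))
      pool <- panel$genus_ids
    }
    if (length(pool) >= need) {
      sel <- select_representatives(pool, profiles, rounds = sel_cfg$rounds)
      ctrl_prof <- prof_ids[seq_len(min(sel_cfg$n_control_profiles,
                                        length(prof_ids)))]
      sel <- remove_dominants(sel, ctrl_prof)
      sector <- normalizing_sector(sel)
    } else {
      note("panel too small for representative selection; stage skipped")
    }
  }

  report <- structure(list(
    config = config, seed = seed,
    n_samples = nrow(tbl$counts), panel_size = length(panel$genus_ids),
    panel = panel, reference = reference, ch_scan = scan,
    phylum_summary = phyla, grid = grid, calls = calls, shifts = shifts,
    differential = differential, diversity = div,
    diversity_comparison = div_compare, selection = sel,
    normalizing_sector = sector, truth = truth, table = tbl,
    warnings = warnings), class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Interleave one full-trajectory rat per enterotype across time points
# (E1_t0, E2_t0, E1_t1, E2_t1, ...) to form the profile order for the
# stepwise selection; NULL when either enterotype lacks a full trajectory.
selection_profiles <- function(md, rat_etype) {
  fec <- md[md$environment == "fecal", , drop = FALSE]
  tps <- unique(fec$time_point)
  tps <- tps[order(time_point_days(tps))]
  pick_rat <- function(e) {
    rats <- names(rat_etype)[rat_etype == e]
    # prefer a triple-dose rat (full dosing trajectory)
    for (g in c("multiple", "single")) {
      cand <- sort(intersect(rats, fec$rat_id[fec$group == g]))
      for (r in cand) {
        if (all(tps %in% fec$time_point[fec$rat_id == r])) return(r)
      }
    }
    NULL
  }
  e_levels <- sort(unique(rat_etype))
  if (length(e_levels) < 2) return(NULL)
  r1 <- pick_rat(e_levels[[1]]); r2 <- pick_rat(e_levels[[2]])
  if (is.null(r1) || is.null(r2)) return(NULL)
  ids <- as.vector(t(outer(tps, c(r1, r2),
                           function(tp, r) paste0(r, "_", tp))))
  intersect(ids, md$sample_id)
}

#' Per-rat enterotype trajectory with shift flags
#'
#' Joins vote-based calls with sample metadata and flags, per rat and time
#' point, whether the call differs from the rat's control call
#' (`"shifted"`), matches it (`"same"`), or is `"unstable"`.
#'
#' @param calls Data frame from [call_all_enterotypes()].
#' @param metadata Sample metadata.
#' @return Data frame with `rat_id`, `time_point`, `sample_id`,
#'   `control_call`, `call`, `status`.
#' @export
shift_table <- function(calls, metadata) {
  md <- as.data.frame(metadata)
  m <- merge(calls[, c("sample_id", "decision")],
             md[, c("sample_id", "rat_id", "time_point", "is_control")],
             by = "sample_id")
  if (length(unique(m$time_point)) < 2)
    stop_es("shift_table needs calls for at least two time points")
  ctrl_call <- stats::setNames(m$decision[m$is_control],
                               m$rat_id[m$is_control])
  m$control_call <- unname(ctrl_call[m$rat_id])
  m$status <- ifelse(m$decision == "unstable", "unstable",
              ifelse(is.na(m$control_call), NA_character_,
              ifelse(m$decision == m$control_call, "same", "shifted")))
  out <- m[order(m$rat_id, time_point_days(m$time_point)),
           c("rat_id", "time_point", "sample_id", "control_call",
             "decision", "status")]
  names(out)[names(out) == "decision"] <- "call"
  rownames(out) <- NULL
  out
}

#' Write pipeline artifacts to a directory
#'
#' Emits deterministic TSV/JSON files (counts, metadata, panel, phylum
#' summary, silhouette grid with S x 100 rounded to integers, calls, shift
#' table, volcano tables, diversity, selection, report summary).  Each TSV
#' carries a header comment with the package version and seed.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- paste0("enteroshift ",
                as.character(utils::packageVersion("enteroshift")),
                " seed=", report$seed)
  p <- function(f) file.path(out_dir, f)
  write_counts(report$table, p("counts.tsv"), p("metadata.tsv"))
  if (!is.null(report$truth)) export_ground_truth(report$truth, p("truth.tsv"))
  write_tsv_det(data.frame(genus = report$panel$genus_ids), p("panel.tsv"), hdr)
  write_tsv_det(report$phylum_summary, p("phylum_summary.tsv"), hdr)
  s100 <- round(report$grid$S * 100)
  write_tsv_det(data.frame(combination = rownames(s100),
                           as.data.frame(s100, check.names = FALSE),
                           check.names = FALSE),
                p("silhouette_grid.tsv"), hdr)
  write_tsv_det(report$calls, p("enterotype_calls.tsv"), hdr)
  write_tsv_det(report$shifts, p("shift_table.tsv"), hdr)
  for (e in names(report$differential)) {
    res <- report$differential[[e]]
    if (is.null(res) || !nrow(res)) next
    write_tsv_det(volcano_table(res), p(paste0("volcano_", e, ".tsv")), hdr)
  }
  write_tsv_det(report$diversity, p("diversity.tsv"), hdr)
  if (!is.null(report$selection)) {
    sel_df <- data.frame(order = seq_along(report$selection$taxa),
                         genus = report$selection$taxa,
                         t(report$selection$profiles[, report$selection$taxa,
                                                     drop = FALSE]),
                         check.names = FALSE)
    write_tsv_det(sel_df, p("selection.tsv"), hdr)
  }
  summary <- list(
    seed = report$seed, n_samples = report$n_samples,
    panel_size = report$panel_size,
    optimal_k = report$ch_scan$optimal_k,
    n_combinations = length(report$grid$combinations),
    enterotype_counts = as.list(table(report$reference)),
    n_unstable = sum(report$calls$decision == "unstable"),
    warnings = report$warnings)
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("enteroshift run_report\n",
      " samples: ", x$n_samples, "; marker panel: ", x$panel_size,
      " genera\n",
      " CH-optimal k (controls): ", x$ch_scan$optimal_k, "\n",
      " reference enterotypes: ",
      paste(names(table(x$reference)), table(x$reference),
            sep = "=", collapse = ", "), "\n",
      " pooled combinations: ", length(x$grid$combinations),
      "; unstable calls: ", sum(x$calls$decision == "unstable"), "\n",
      sep = "")
  if (length(x$warnings))
    cat(" warnings:\n", paste0("  - ", x$warnings, "\n"), sep = "")
  invisible(x)
}
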