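#' Default per-enterotype phylum composition targets
#'
#' Expected percent of total reads per phylum for the two community templates.
#' The two enterotypes are separated mainly by the Bacteroidota/Bacillota
#' (B/F) mass ratio (2.06 for E1, 2.1 for E2 at baseline) and by the
#' Verrucomicrobiota load, which is marginal in E1 and a few percent in E2.
#'
#' @return Named list with elements `E1` and `E2`, each a named numeric
#'   vector of phylum percentages summing to 100.
#' @export
default_phylum_targets <- function() {
  list(
    E1 = c(Bacteroidota = 55.6, Bacillota = 27.0, Verrucomicrobiota = 0.1,
           Pseudomonadota = 8.0, Actinomycetota = 4.0, other = 5.3),
    E2 = c(Bacteroidota = 56.7, Bacillota = 27.0, Verrucomicrobiota = 3.3,
           Pseudomonadota = 6.0, Actinomycetota = 3.0, other = 4.0)
  )
}

# Real genus names seeded into the synthetic taxonomy so that planted
# probiotic trajectories (lactobacilli, bifidobacteria, persistent
# responders) can be addressed by name.
.known_genera <- list(
  Bacteroidota = c("Muribaculum", "Prevotella", "Bacteroides",
                   "Parabacteroides", "Barnesiella", "Paraprevotella",
                   "Phocaeicola", "Alistipes"),
  Bacillota = c("Lacticaseibacillus", "Blautia", "Flintibacter",
                "Lachnoclostridium", "Flavonifractor", "Oscillibacter",
                "Ruthenibacterium", "Anaerostipes", "Eubacterium",
                "Roseburia", "Faecalibacterium", "Clostridium"),
  Verrucomicrobiota = c("Akkermansia"),
  Pseudomonadota = c("Escherichia", "Klebsiella", "Parasutterella"),
  Actinomycetota = c("Bifidobacterium", "Collinsella")
)

#' Build a two-enterotype community template
#'
#' Constructs genus names, a genus-to-phylum map and per-enterotype Dirichlet
#' concentration (relative-mass) vectors whose phylum mass fractions match
#' `phylum_targets` exactly.  Within each phylum, genus masses follow a
#' rank-based power law; the rank order is permuted independently per
#' enterotype (with the dominant Bacteroidota genus pinned to Muribaculum in
#' E1 and Prevotella in E2) so the two templates are separable at the genus
#' level even where their phylum profiles are similar.
#'
#' @param n_genera Number of genera (at least the number of phyla).
#' @param phylum_targets Named list of per-enterotype phylum percentage
#'   vectors, as [default_phylum_targets()].  Each must sum to 100 (+/- 0.1).
#' @param seed Integer seed; a fixed seed yields an identical template.
#' @param power Exponent of the within-phylum rank-abundance power law.
#' @return An object of class `community_template`: list with `genus_names`,
#'   `phylum_of`, `base_concentration` (enterotype x genus matrix of
#'   relative masses, rows summing to 1), `enterotype_labels`,
#'   `phylum_targets`.
#' @export
build_template <- function(n_genera = 220,
                           phylum_targets = default_phylum_targets(),
                           seed = 1, power = 1.2) {
  stopifnot(is.list(phylum_targets), length(phylum_targets) == 2)
  etypes <- names(phylum_targets)
  phyla <- names(phylum_targets[[1]])
  for (tg in phylum_targets) {
    if (!identical(sort(names(tg)), sort(phyla)))
      stop_es("phylum_targets must use the same phylum names for both enterotypes")
    if (abs(sum(tg) - 100) > 0.1)
      stop_es("phylum_targets must sum to 100 (+/- 0.1)")
    if (any(tg < 0)) stop_es("phylum targets must be nonnegative")
  }
  if (n_genera < length(phyla))
    stop_es("invalid template: n_genera < number of phyla")

  # allocate genus slots per phylum ~ sqrt(mean target mass), min 1 each
  mean_mass <- colMeans(do.call(rbind, phylum_targets)[, phyla, drop = FALSE])
  share <- sqrt(pmax(mean_mass, 1e-3))
  slots <- floor(share / sum(share) * n_genera)
  slots[slots < 1] <- 1
  while (sum(slots) > n_genera) slots[which.max(slots)] <- slots[which.max(slots)] - 1L
  while (sum(slots) < n_genera) slots[which.max(share / slots)] <- slots[which.max(share / slots)] + 1L

  genus_names <- character(0)
  phylum_of <- character(0)
  for (ph in phyla) {
    known <- .known_genera[[ph]] %||% character(0)
    k <- min(length(known), slots[[ph]])
    nm <- known[seq_len(k)]
    n_extra <- slots[[ph]] - k
    if (n_extra > 0)
      nm <- c(nm, sprintf("%s_g%03d", ph, seq_len(n_extra)))
    genus_names <- c(genus_names, nm)
    phylum_of <- c(phylum_of, stats::setNames(rep(ph, slots[[ph]]), nm))
  }

  conc <- with_seed(seed, {
    m <- matrix(0, nrow = 2, ncol = length(genus_names),
                dimnames = list(etypes, genus_names))
    for (e in etypes) {
      for (ph in phyla) {
        members <- genus_names[phylum_of[genus_names] == ph]
        n_m <- length(members)
        w <- (seq_len(n_m))^(-power)
        ord <- sample.int(n_m)
        # pin the dominant Bacteroidota genus per enterotype
        pin <- if (ph == "Bacteroidota") {
          if (e == etypes[[1]]) "Muribaculum" else "Prevotella"
        } else NA_character_
        if (!is.na(pin) && pin %in% members) {
          i_pin <- match(pin, members)
          i_top <- which(ord == 1L)
          ord[c(i_top, i_pin)] <- ord[c(i_pin, i_top)]
        }
        w_assigned <- w[ord]
        m[e, members] <- w_assigned / sum(w_assigned) *
          phylum_targets[[e]][[ph]] / 100
      }
      m[e, ] <- m[e, ] / sum(m[e, ])
    }
    m
  })

  out <- structure(list(genus_names = genus_names,
                        phylum_of = phylum_of,
                        base_concentration = conc,
                        enterotype_labels = etypes,
                        phylum_targets = phylum_targets),
                   class = "community_template")
  validate_template(out)
  out
}

validate_template <- function(tpl) {
  conc <- tpl$base_concentration
  if (any(conc <= 0)) stop_es("invalid template: nonpositive concentrations")
  bf <- c("Bacteroidota", "Bacillota")
  if (all(bf %in% unique(tpl$phylum_of))) {
    for (e in rownames(conc)) {
      mass <- sum(conc[e, tpl$phylum_of[tpl$genus_names] %in% bf])
      if (mass < 0.5)
        stop_es("invalid template: Bacteroidota+Bacillota mass below 50% for ", e)
    }
  }
  invisible(tpl)
}

#' Expected phylum percentages of a template
#'
#' @param tpl A `community_template`.
#' @return Matrix (enterotype x phylum) of expected percent mass.
#' @export
template_phylum_mass <- function(tpl) {
  phyla <- unique(tpl$phylum_of)
  out <- sapply(phyla, function(ph) {
    rowSums(tpl$base_concentration[, tpl$phylum_of[tpl$genus_names] == ph,
                                   drop = FALSE]) * 100
  })
  out
}

#' Construct a planted probiotic effect model
#'
#' @param effects Data frame with columns `genus`, `enterotype`,
#'   `dose_index` (1, 2 or 3) and `log2_effect`.
#' @param persistence Named numeric vector, genus -> effect half-life in
#'   days (strictly positive).  Genera absent from it get `default_half_life`.
#' @param probiotic_genera Named character vector identifying the planted
#'   lactobacilli / bifidobacteria genera.
#' @param default_half_life Half-life (days) for genera not listed in
#'   `persistence`.
#' @return Object of class `effect_model`.
#' @export
effect_model <- function(effects,
                         persistence = numeric(0),
                         probiotic_genera = c(lactobacilli = "Lacticaseibacillus",
                                              bifidobacteria = "Bifidobacterium"),
                         default_half_life = 3) {
  effects <- as.data.frame(effects)
  need <- c("genus", "enterotype", "dose_index", "log2_effect")
  if (!all(need %in% names(effects)))
    stop_es("effects must have columns ", paste(need, collapse = ", "))
  if (nrow(effects) && !all(effects$dose_index %in% 1:3))
    stop_es("dose_index must be in {1, 2, 3}")
  if (any(persistence <= 0) || default_half_life <= 0)
    stop_es("persistence half-lives must be positive")
  structure(list(effects = effects, persistence = persistence,
                 probiotic_genera = probiotic_genera,
                 default_half_life = default_half_life),
            class = "effect_model")
}

#' Null (no-effect) model
#' @export
#' @rdname effect_model
null_effect_model <- function() {
  effect_model(data.frame(genus = character(0), enterotype = character(0),
                          dose_index = integer(0), log2_effect = numeric(0)))
}

#' Default planted effect model for a template
#'
#' Plants the probiotic trajectories the analysis is meant to detect:
#' lactobacilli expand after dosing (immediately in E2, only after the third
#' dose in E1) while bifidobacteria are suppressed in E2 and transiently in
#' E1; a Barnesiella-like E2 responder carries a long half-life (persistent
#' suppression); and a block of further responder genera receives
#' dose-dependent log2 effects, several with opposite signs in the two
#' enterotypes.
#'
#' @param tpl A `community_template`.
#' @param n_responders Number of additional (non-probiotic) responder genera.
#' @param seed Seed used to pick the responder genera.
#' @return An `effect_model`.
#' @export
default_effect_model <- function(tpl, n_responders = 16, seed = 1) {
  e1 <- tpl$enterotype_labels[[1]]; e2 <- tpl$enterotype_labels[[2]]
  rows <- list()
  add <- function(genus, enterotype, dose, eff) {
    rows[[length(rows) + 1L]] <<- data.frame(
      genus = genus, enterotype = enterotype,
      dose_index = dose, log2_effect = eff)
  }
  if ("Lacticaseibacillus" %in% tpl$genus_names) {
    add("Lacticaseibacillus", e1, 1, -0.5)
    add("Lacticaseibacillus", e1, 2, -0.5)
    add("Lacticaseibacillus", e1, 3, 2.0)
    add("Lacticaseibacillus", e2, 1, 2.0)
  }
  if ("Bifidobacterium" %in% tpl$genus_names) {
    add("Bifidobacterium", e1, 2, -1.0)
    add("Bifidobacterium", e1, 3, 1.5)
    add("Bifidobacterium", e2, 1, -1.5)
  }
  if ("Barnesiella" %in% tpl$genus_names) add("Barnesiella", e2, 1, -1.5)

  special <- c("Lacticaseibacillus", "Bifidobacterium", "Barnesiella")
  pool <- setdiff(tpl$genus_names, special)
  # prefer reasonably abundant genera so effects are observable at desk depth
  mean_mass <- colMeans(tpl$base_concentration)[pool]
  pool <- pool[order(-mean_mass)][seq_len(min(60, length(pool)))]
  picked <- with_seed(seed, sample(pool, min(n_responders, length(pool))))
  for (i in seq_along(picked)) {
    sgn1 <- if (i %% 2 == 0) 1 else -1
    sgn2 <- if (i %% 4 < 2) sgn1 else -sgn1  # half flip sign in E2
    for (d in 1:3) add(picked[[i]], e1, d, sgn1 * (0.5 + 0.5 * d))
    add(picked[[i]], e2, 1, sgn2 * 1.2)
  }
  persistence <- c(Lacticaseibacillus = 20, Bifidobacterium = 30,
                   Barnesiella = 60)
  persistence <- persistence[names(persistence) %in% tpl$genus_names]
  effect_model(do.call(rbind, rows), persistence = persistence)
}

#' Describe a synthetic cohort design
#'
#' @param n_rats_per_enterotype Named counts of rats per enterotype.
#' @param n_multiple Named counts of rats (per enterotype) assigned to the
#'   triple-dose "multiple" group; the remainder are "single"-dose.
#' @param time_points Ordered sampling labels; must start at `"0h"` (the
#'   per-rat control sample).
#' @param depth Reads per sample (>= 1000).
#' @param rat_overdispersion Dirichlet concentration scale for rat-level
#'   baseline draws around the enterotype template.
#' @param seed Integer seed driving every random draw of the simulation.
#' @return Object of class `synthetic_design` with a `rats` data frame.
#' @export
synthetic_design <- function(n_rats_per_enterotype = c(E1 = 14, E2 = 7),
                             n_multiple = c(E1 = 12, E2 = 0),
                             time_points = c("0h", "24h", "48h", "72h", "14d"),
                             depth = 30000,
                             rat_overdispersion = 200,
                             seed = 1) {
  if (depth < 1000) stop_es("depth must be >= 1000")
  if (time_points[[1]] != "0h")
    stop_es("time_points must start at 0h (the control sample)")
  etypes <- names(n_rats_per_enterotype)
  rats <- do.call(rbind, lapply(etypes, function(e) {
    n <- n_rats_per_enterotype[[e]]
    if (n == 0) return(NULL)
    n_m <- min(n_multiple[e] %||% 0, n)
    if (is.na(n_m)) n_m <- 0
    data.frame(rat_id = sprintf("%s_r%02d", tolower(e), seq_len(n)),
               enterotype = e,
               group = c(rep("multiple", n_m), rep("single", n - n_m)))
  }))
  structure(list(rats = rats, time_points = time_points, depth = depth,
                 rat_overdispersion = rat_overdispersion, seed = seed),
            class = "synthetic_design")
}

#' Parse time-point labels into days
#' @param tp Character labels such as `"0h"`, `"72h"`, `"14d"`.
#' @return Numeric days.
#' @export
time_point_days <- function(tp) {
  n <- as.numeric(sub("[hd]$", "", tp))
  ifelse(grepl("h$", tp), n / 24, n)
}

# Dose schedule in days for a dosing group: dose d is given at day d-1.
dose_days <- function(group) {
  switch(group, single = 0, multiple = c(0, 1, 2),
         stop_es("unknown dosing group: ", group))
}

# Cumulative planted log2 multiplier per genus at sample day t.
# A dose takes full effect over the following day and then decays
# exponentially with the genus half-life.
cumulative_log2_effect <- function(genus_names, enterotype, group, t_day,
                                   effects) {
  lm <- stats::setNames(numeric(length(genus_names)), genus_names)
  eff <- effects$effects
  eff <- eff[eff$enterotype == enterotype, , drop = FALSE]
  if (!nrow(eff)) return(lm)
  dd <- dose_days(group)
  for (d in seq_along(dd)) {
    if (t_day <= dd[[d]]) next         # dose not yet administered
    rows <- eff[eff$dose_index == d, , drop = FALSE]
    if (!nrow(rows)) next
    hl <- ifelse(rows$genus %in% names(effects$persistence),
                 effects$persistence[rows$genus],
                 effects$default_half_life)
    lag <- pmax(0, t_day - dd[[d]] - 1)
    decay <- 2^(-lag / hl)
    lm[rows$genus] <- lm[rows$genus] + rows$log2_effect * decay
  }
  lm
}

#' Simulate a probiotic-dosing cohort
#'
#' Each rat receives a Dirichlet baseline drawn around its enterotype
#' template (concentration `rat_overdispersion * base_concentration`).  At a
#' sample day t the composition is the baseline multiplied per genus by
#' `2^(cumulative dosed log2 effect x decay)` and renormalized; reads are a
#' single multinomial draw at `design$depth`.
#'
#' @param design A `synthetic_design`.
#' @param template A `community_template`.
#' @param effects An `effect_model` (use [null_effect_model()] for controls).
#' @return List with `table` (a `count_table`, see [count_table()]) and
#'   `truth` (class `ground_truth`: rat enterotypes plus the planted effect
#'   table and half-lives).
#' @export
simulate_cohort <- function(design, template,
                            effects = null_effect_model()) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(template, "community_template"),
            inherits(effects, "effect_model"))
  unknown <- setdiff(effects$effects$genus, template$genus_names)
  if (length(unknown))
    stop_es("effect model references unknown genera: ",
            paste(unknown, collapse = ", "))
  genus <- template$genus_names
  rats <- design$rats
  tps <- design$time_points
  t_days <- time_point_days(tps)

  with_seed(design$seed, {
    counts <- matrix(0L, nrow = nrow(rats) * length(tps), ncol = length(genus))
    meta <- vector("list", nrow(rats) * length(tps))
    sample_ids <- character(nrow(counts))
    row <- 0L
    for (i in seq_len(nrow(rats))) {
      e <- rats$enterotype[[i]]
      baseline <- rdirichlet1(design$rat_overdispersion *
                                template$base_concentration[e, ])
      for (j in seq_along(tps)) {
        lm <- cumulative_log2_effect(genus, e, rats$group[[i]], t_days[[j]],
                                     effects)
        p <- baseline * 2^lm
        p <- p / sum(p)
        row <- row + 1L
        counts[row, ] <- as.integer(stats::rmultinom(1, design$depth, p))
        sample_ids[[row]] <- paste0(rats$rat_id[[i]], "_", tps[[j]])
        meta[[row]] <- data.frame(
          sample_id = sample_ids[[row]], rat_id = rats$rat_id[[i]],
          group = rats$group[[i]], time_point = tps[[j]],
          environment = "fecal", is_control = tps[[j]] == "0h",
          known_enterotype = e)
      }
    }
    dimnames(counts) <- list(sample_ids, genus)
    tbl <- count_table(counts, do.call(rbind, meta))
    truth <- structure(list(rats = rats, effects = effects$effects,
                            persistence = effects$persistence,
                            default_half_life = effects$default_half_life),
                       class = "ground_truth")
    list(table = tbl, truth = truth)
  })
}

#' Write / read simulator ground truth
#'
#' Serializes rat enterotype assignments and the planted effect table to a
#' single long-format TSV that round-trips losslessly through
#' [read_ground_truth()].
#'
#' @param gt A `ground_truth` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  rat_rows <- data.frame(record = "rat", genus = NA_character_,
                         enterotype = gt$rats$enterotype,
                         dose_index = NA_integer_, value = NA_real_,
                         rat_id = gt$rats$rat_id, group = gt$rats$group)
  eff <- gt$effects
  eff_rows <- if (nrow(eff)) {
    data.frame(record = "effect", genus = eff$genus,
               enterotype = eff$enterotype, dose_index = eff$dose_index,
               value = eff$log2_effect, rat_id = NA_character_,
               group = NA_character_)
  } else NULL
  per_rows <- if (length(gt$persistence)) {
    data.frame(record = "persistence", genus = names(gt$persistence),
               enterotype = NA_character_, dose_index = NA_integer_,
               value = unname(gt$persistence), rat_id = NA_character_,
               group = NA_character_)
  } else NULL
  hl_row <- data.frame(record = "default_half_life", genus = NA_character_,
                       enterotype = NA_character_, dose_index = NA_integer_,
                       value = gt$default_half_life, rat_id = NA_character_,
                       group = NA_character_)
  write_tsv_det(rbind(rat_rows, eff_rows, per_rows, hl_row), path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read_table_auto(path)
  rats <- df[df$record == "rat", c("rat_id", "enterotype", "group")]
  rownames(rats) <- NULL
  eff <- df[df$record == "effect", c("genus", "enterotype", "dose_index", "value")]
  names(eff)[names(eff) == "value"] <- "log2_effect"
  eff$dose_index <- as.integer(eff$dose_index)
  rownames(eff) <- NULL
  per <- df[df$record == "persistence", ]
  persistence <- stats::setNames(per$value, per$genus)
  if (!length(persistence)) persistence <- numeric(0)
  structure(list(rats = rats, effects = eff, persistence = persistence,
                 default_half_life = df$value[df$record == "default_half_life"][[1]]),
            class = "ground_truth")
}
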