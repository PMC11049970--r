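# Shared fixtures and independent oracles for the test suite.

# Tiny count table: 3 samples x 3 genera with exact integer counts.
toy_counts <- function() {
  m <- matrix(c(90L, 5L, 5L,
                50L, 25L, 25L,
                10L, 45L, 45L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("X", "A", "B")))
  count_table(m, data.frame(sample_id = c("s1", "s2", "s3"),
                            rat_id = c("r1", "r2", "r3"),
                            group = "single",
                            time_point = "0h",
                            environment = "fecal",
                            is_control = TRUE))
}

# Metadata for one rat with the full five-point trajectory.
trajectory_metadata <- function(rat = "r1", group = "single",
                                enterotype = "E1") {
  tps <- c("0h", "24h", "48h", "72h", "14d")
  data.frame(sample_id = paste0(rat, "_", tps), rat_id = rat, group = group,
             time_point = tps, environment = "fecal",
             is_control = tps == "0h", known_enterotype = enterotype)
}

# Independent JSD oracle: literal term-by-term evaluation of the two KL sums.
jsd_oracle <- function(p, q, log_fun = log) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log_fun(a[i] / b[i])
    s
  }
  sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
}

# Brute-force PAM oracle: exhaustive enumeration of all medoid sets.
brute_force_pam <- function(dm, k) {
  n <- nrow(dm)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(dm[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# Direct per-sample silhouette computation (independent of the package's
# vectorization): follows the textbook definition literally.
silhouette_oracle <- function(dm, labels) {
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(dm[i, own])
    b <- Inf
    for (kk in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(dm[i, labels == kk]))
    s[i] <- (b - a) / max(a, b)
  }
  names(s) <- rownames(dm)
  s
}

# Distance matrix of two tight, well-separated pairs (plus optional noise).
two_pair_distance <- function() {
  d <- matrix(c(0, 0.01, 1, 1,
                0.01, 0, 1, 1,
                1, 1, 0, 0.01,
                1, 1, 0.01, 0),
              nrow = 4, dimnames = list(letters[1:4], letters[1:4]))
  d
}

# Small random composition matrix under a fixed seed.
random_compositions <- function(n, g, seed) {
  set.seed(seed)
  m <- matrix(rgamma(n * g, shape = 0.5), nrow = n,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("g", seq_len(g))))
  sweep(m, 1, rowSums(m), "/")
}

# Expected perturbed composition calculator, independent of the simulator:
# applies the planted log2 multipliers to a baseline and renormalizes.
expected_composition <- function(baseline, log2_mult) {
  w <- baseline * 2^log2_mult
  w / sum(w)
}

# Default small template/design for fast simulations in tests.
small_template <- function(seed = 1) build_template(n_genera = 60, seed = seed)

small_design <- function(seed = 1, depth = 30000,
                         n_rats = c(E1 = 4, E2 = 3),
                         n_multiple = c(E1 = 2, E2 = 0)) {
  synthetic_design(n_rats_per_enterotype = n_rats, n_multiple = n_multiple,
                   depth = depth, seed = seed)
}
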