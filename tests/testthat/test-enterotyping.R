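test_that("JSD matches closed forms and the term-by-term oracle", {
  m <- rbind(a = c(0.5, 0.5), b = c(0.5, 0.5))
  expect_equal(jsd_distance(m)$d["a", "b"], 0)
  # disjoint supports approach the sqrt(log 2) bound
  m2 <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(jsd_distance(m2)$d["a", "b"], sqrt(log(2)), tolerance = 1e-3)
  m3 <- rbind(a = c(0.5, 0.5), b = c(0.25, 0.75))
  expect_equal(jsd_distance(m3)$d["a", "b"],
               jsd_oracle(c(0.5, 0.5), c(0.25, 0.75)))
  expect_equal(jsd_distance(m3, log_base = "2")$d["a", "b"],
               jsd_oracle(c(0.5, 0.5), c(0.25, 0.75), log2))
  expect_error(jsd_distance(rbind(a = c(-1, 2), b = c(1, 1))), "negative")
})

test_that("JSD satisfies the metric axioms on random compositions", {
  p <- random_compositions(200, 25, seed = 17)
  # pairwise over a rotating subset keeps this O(hundreds) of triples
  idx <- matrix(sample.int(200, 300, replace = TRUE), ncol = 3)
  bound <- sqrt(log(2)) + 1e-9
  d <- jsd_distance(p[unique(as.vector(idx)), , drop = FALSE])$d
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= bound))
  for (r in seq_len(nrow(idx))) {
    i <- rownames(p)[idx[r, 1]]; j <- rownames(p)[idx[r, 2]]
    k <- rownames(p)[idx[r, 3]]
    if (length(unique(c(i, j, k))) < 3) next
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("PAM recovers separable pairs and matches brute force for small n", {
  d <- two_pair_distance()
  part <- pam_partition(d, 2)
  expect_equal(part$labels[["a"]], part$labels[["b"]])
  expect_equal(part$labels[["c"]], part$labels[["d"]])
  expect_true(part$labels[["a"]] != part$labels[["c"]])
  # objective equals the exhaustive optimum on random matrices with n <= 8
  for (seed in 1:6) {
    p <- random_compositions(sample(5:8, 1), 12, seed = seed)
    dm <- jsd_distance(p)$d
    for (k in 2:3) {
      part <- pam_partition(dm, k)
      expect_equal(pam_objective(dm, part), brute_force_pam(dm, k),
                   tolerance = 1e-12,
                   info = paste("seed", seed, "k", k))
    }
  }
  # duplicated samples land in the same cluster
  p <- random_compositions(5, 10, seed = 3)
  p <- rbind(p, dup = p["s1", ])
  dm <- jsd_distance(p)$d
  part <- pam_partition(dm, 2)
  expect_equal(part$labels[["s1"]], part$labels[["dup"]])
  expect_error(pam_partition(d, 4), "invalid k")
  expect_error(pam_partition(d, 1), "invalid k")
})

test_that("CH scan picks the planted number of clusters", {
  # two well-separated planted clusters
  d2 <- as.matrix(dist(c(rnorm(6, 0, 0.02), rnorm(6, 5, 0.02))))
  dimnames(d2) <- list(paste0("s", 1:12), paste0("s", 1:12))
  scan2 <- ch_scan(d2, 2:5)
  expect_equal(scan2$optimal_k, 2)
  # three equidistant groups replicated 5x
  lab <- rep(1:3, each = 5)
  d3 <- matrix(1, 15, 15, dimnames = list(paste0("s", 1:15), paste0("s", 1:15)))
  d3[outer(lab, lab, "==")] <- 0.05
  diag(d3) <- 0
  scan3 <- ch_scan(d3, 2:5)
  expect_equal(scan3$optimal_k, 3)
  expect_true(all(is.finite(scan3$ch_index) & scan3$ch_index > 0))
  expect_error(ch_scan(d2[1:3, 1:3]), "insufficient")
})

test_that("silhouette matches the direct definition and its bounds", {
  d <- two_pair_distance()
  part <- pam_partition(d, 2)
  s <- silhouette_scores(d, part)
  expect_true(all(s > 0.9))
  # sample equidistant from both clusters scores zero
  d5 <- matrix(c(0, 0.1, 1, 1, 0.55,
                 0.1, 0, 1, 1, 0.55,
                 1, 1, 0, 0.1, 0.55,
                 1, 1, 0.1, 0, 0.55,
                 0.55, 0.55, 0.55, 0.55, 0), 5, 5,
               dimnames = list(letters[1:5], letters[1:5]))
  part5 <- list(labels = setNames(c(1L, 1L, 2L, 2L, 1L), letters[1:5]),
                medoids = setNames(c("a", "c"), 1:2), k = 2L)
  class(part5) <- "partition"
  s5 <- silhouette_scores(d5, part5)
  expect_equal(unname(s5["e"]), 0, tolerance = 1e-12)
  # agreement with an independent per-sample computation on a 6-sample fixture
  p <- random_compositions(6, 8, seed = 23)
  dm <- jsd_distance(p)$d
  part6 <- pam_partition(dm, 3)
  expect_equal(silhouette_scores(dm, part6),
               silhouette_oracle(dm, part6$labels[rownames(dm)]))
  # cross-check against the cluster package on the same fixture
  sil <- cluster::silhouette(part6$labels[rownames(dm)], stats::as.dist(dm))
  expect_equal(unname(silhouette_scores(dm, part6)),
               unname(sil[, "sil_width"]), tolerance = 1e-12)
  expect_true(all(silhouette_scores(dm, part6) >= -1 &
                    silhouette_scores(dm, part6) <= 1))
})

test_that("pooled set enumeration yields all combinations of size >= 2", {
  five <- enumerate_pooled_sets(c("con", "24h", "48h", "72h", "14d"))
  sizes <- table(lengths(five))
  expect_equal(as.integer(sizes[c("2", "3", "4", "5")]), c(10L, 10L, 5L, 1L))
  expect_equal(length(five), 26)
  expect_equal(length(enumerate_pooled_sets(c("a", "b"))), 1)
  expect_equal(length(enumerate_pooled_sets(letters[1:4])), 11)  # 6 + 4 + 1
  expect_error(enumerate_pooled_sets("a"), "at least two")
  # deterministic naming and order
  expect_identical(names(five)[1], "con_24h")
  expect_identical(names(five)[26], "con_24h_48h_72h_14d")
})

# Build a small two-enterotype scenario with explicit compositions:
# controls cluster cleanly; an optional "shifted" set moves the E1 rats'
# later samples onto E2-like compositions.
grid_scenario <- function(shift = FALSE, seed = 31) {
  set.seed(seed)
  tpl <- build_template(n_genera = 60, seed = seed)
  draw <- function(e, n, ids) {
    m <- t(replicate(n, enteroshift:::rdirichlet1(
      200 * tpl$base_concentration[e, ]))) * 100
    rownames(m) <- ids
    colnames(m) <- tpl$genus_names
    m
  }
  rats_e1 <- paste0("e1r", 1:4); rats_e2 <- paste0("e2r", 1:3)
  con <- rbind(draw("E1", 4, paste0(rats_e1, "_0h")),
               draw("E2", 3, paste0(rats_e2, "_0h")))
  later_e1 <- draw(if (shift) "E2" else "E1", 4, paste0(rats_e1, "_72h"))
  later_e2 <- draw("E2", 3, paste0(rats_e2, "_72h"))
  later <- rbind(later_e1, later_e2)
  reference <- setNames(rep(c("E1", "E2"), c(4, 3)), rownames(con))
  rat_of <- setNames(rep(c(rats_e1, rats_e2), 2),
                     c(rownames(con), rownames(later)))
  list(ab = list(con = con, `72h` = later), reference = reference,
       rat_of = rat_of)
}

test_that("stability grid scores samples only where present and self-consistently", {
  sc <- grid_scenario(shift = FALSE)
  grid <- stability_grid(sc$ab, sc$reference, rat_of = sc$rat_of)
  expect_s3_class(grid, "silhouette_grid")
  expect_equal(rownames(grid$S), "con_72h")
  # every pooled sample scored, none absent for a 2-set scenario
  expect_true(all(!is.na(grid$S)))
  expect_true(all(grid$S >= -1 & grid$S <= 1))
  # without a planted shift the harmonized labels reproduce the reference
  expect_equal(unname(grid$label["con_72h", names(sc$reference)]),
               unname(sc$reference))
})

test_that("a planted E2-ward shift flips harmonized labels of shifted cells only", {
  sc <- grid_scenario(shift = TRUE)
  grid <- stability_grid(sc$ab, sc$reference, rat_of = sc$rat_of)
  lab <- grid$label["con_72h", ]
  # controls keep their reference labels
  expect_equal(unname(lab[names(sc$reference)]), unname(sc$reference))
  # E1 rats' 72h samples now co-cluster with E2
  shifted <- paste0("e1r", 1:4, "_72h")
  expect_true(all(lab[shifted] == "E2"))
})

test_that("harmonization is invariant to sample-row permutation", {
  sc <- grid_scenario(shift = FALSE, seed = 5)
  g1 <- stability_grid(sc$ab, sc$reference, rat_of = sc$rat_of)
  perm <- lapply(sc$ab, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
  g2 <- stability_grid(perm, sc$reference, rat_of = sc$rat_of)
  cols <- colnames(g1$label)
  expect_equal(g1$label[, cols], g2$label[, cols])
  expect_equal(g1$S[, cols], g2$S[, cols], tolerance = 1e-12)
})

test_that("the vote rule counts only true assignments above the threshold", {
  mk_grid <- function(S, label) {
    structure(list(
      S = matrix(S, ncol = 1, dimnames = list(paste0("c", seq_along(S)), "x")),
      label = matrix(label, ncol = 1,
                     dimnames = list(paste0("c", seq_along(S)), "x")),
      combinations = as.list(paste0("c", seq_along(S))),
      skipped = character(0)), class = "silhouette_grid")
  }
  # unanimity
  g <- mk_grid(rep(0.4, 6), rep("E2", 6))
  cl <- call_enterotype(g, "x")
  expect_equal(cl$decision, "E2")
  expect_equal(unname(cl$votes), 6)
  # scores at or below 0.1 never count as true
  g2 <- mk_grid(c(0.1, 0.05, -0.2), c("E1", "E1", "E1"))
  expect_equal(call_enterotype(g2, "x")$decision, "unstable")
  # tie rule
  g3 <- mk_grid(rep(0.5, 4), c("E1", "E1", "E2", "E2"))
  expect_equal(call_enterotype(g3, "x")$decision, "unstable")
  # mixed: majority of true assignments wins
  g4 <- mk_grid(c(0.5, 0.5, 0.05, 0.3), c("E1", "E1", "E2", "E2"))
  cl4 <- call_enterotype(g4, "x")
  expect_equal(cl4$decision, "E1")
  expect_equal(unname(cl4$votes), c(2, 1))
  expect_error(call_enterotype(g, "missing"), "unknown sample")
})

test_that("PCoA reproduces distances and degenerate geometry", {
  # three equidistant samples embed as an equilateral triangle
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  xy <- pcoa_coordinates(d3, 2)
  pd <- as.matrix(dist(xy))
  expect_equal(unname(pd[upper.tri(pd)]), rep(1, 3), tolerance = 1e-9)
  # distances reconstructed on a Euclidean-compatible 6-sample fixture
  set.seed(8)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  dm <- as.matrix(dist(pts))
  rec <- as.matrix(dist(pcoa_coordinates(dm, 2)))
  expect_equal(unname(rec), unname(dm), tolerance = 1e-9)
  # duplicate samples coincide
  dm2 <- as.matrix(dist(rbind(pts, s7 = pts["s1", ])))
  xy2 <- pcoa_coordinates(dm2, 2)
  expect_equal(unname(xy2["s7", ]), unname(xy2["s1", ]), tolerance = 1e-9)
  asym <- d3; asym[1, 2] <- 0.5
  expect_error(pcoa_coordinates(asym, 1), "symmetric")
})
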