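test_that("dosing and recovery schemes pair treated samples to the 0h control", {
  md_s <- trajectory_metadata("r1", "single")
  dos <- build_pairs(md_s, "dosing")
  expect_equal(nrow(dos), 1)           # single dose: only 24h is in-dosing
  expect_equal(dos$experimental, "r1_24h")
  expect_equal(dos$control, "r1_0h")
  rec <- build_pairs(md_s, "recovery")
  expect_setequal(rec$experimental, c("r1_48h", "r1_72h", "r1_14d"))
  expect_true(all(rec$control == "r1_0h"))  # one control reused across pairs

  md_m <- trajectory_metadata("r2", "multiple")
  dos_m <- build_pairs(md_m, "dosing")
  expect_setequal(dos_m$experimental, c("r2_24h", "r2_48h", "r2_72h"))
  expect_setequal(dos_m$group_label,
                  c("dose1_24h", "dose2_48h", "dose3_72h"))
  expect_equal(build_pairs(md_m, "recovery")$experimental, "r2_14d")

  # a rat without a 0h control cannot be paired
  md_bad <- md_s[md_s$time_point != "0h", ]
  expect_error(build_pairs(md_bad, "dosing"), "pairing error")
})

test_that("in vitro scheme pairs parallel cultures and honors exclusions", {
  md <- data.frame(
    sample_id = c("6s_GM", "6s_Pr", "5m_GM", "5m_Pr", "7m_GM"),
    rat_id = c("6s", "6s", "5m", "5m", "7m"),
    group = "single",
    time_point = c("24h", "24h", "24h", "24h", "24h"),
    environment = c("GMM", "GMM_probiotic", "GMM", "GMM_probiotic", "GMM"),
    is_control = FALSE)
  pr <- build_pairs(md, "in_vitro")
  expect_equal(nrow(pr), 2)  # 7m has no probiotic counterpart
  expect_true(all(pr$group_label == "invitro_24h"))
  # hand-curated pair exclusion (suspected sample swap)
  pr2 <- build_pairs(md, "in_vitro", exclude = "5m_GM:5m_Pr")
  expect_equal(pr2$control, "6s_GM")
})

test_that("fold-change ratios follow the pseudocounted percentage arithmetic", {
  m <- rbind(c0 = c(A = 50L, B = 9950L), e0 = c(A = 200L, B = 9800L))
  tbl <- count_table(m, data.frame(sample_id = c("c0", "e0")))
  ab <- percentages(tbl, pseudocount = 1)
  pairs <- data.frame(control = "c0", experimental = "e0",
                      group_label = "g")
  rec <- compute_fcr(ab, pairs)
  expect_equal(rec$fcr[rec$genus == "A"], 4)    # 2.0% / 0.5%
  # identical samples give fcr = 1 everywhere
  pairs_id <- data.frame(control = "c0", experimental = "c0",
                         group_label = "g")
  expect_true(all(compute_fcr(ab, pairs_id)$fcr == 1))
  # a zero-count control is pseudocounted: large but finite ratio
  m2 <- rbind(cz = c(A = 0L, B = 10000L), ez = c(A = 3000L, B = 7000L))
  tbl2 <- count_table(m2, data.frame(sample_id = c("cz", "ez")))
  ab2 <- percentages(tbl2, pseudocount = 1)
  rec2 <- compute_fcr(ab2, data.frame(control = "cz", experimental = "ez",
                                      group_label = "g"))
  expect_true(is.finite(rec2$fcr[rec2$genus == "A"]))
  expect_gt(rec2$fcr[rec2$genus == "A"], 1000)
  # pseudocount is mandatory
  expect_error(compute_fcr(percentages(tbl), pairs), "pseudocount = 1")
  expect_error(compute_fcr(ab, data.frame(control = "c0",
                                          experimental = "nope",
                                          group_label = "g")), "missing")
})

test_that("the FCR of a reversed pair is the reciprocal", {
  set.seed(12)
  m <- matrix(rpois(40, 800), nrow = 2,
              dimnames = list(c("x", "y"), paste0("g", 1:20)))
  m[1, 3] <- 0L  # exercise the pseudocount branch on both sides
  tbl <- count_table(m, data.frame(sample_id = c("x", "y")))
  ab <- percentages(tbl, pseudocount = 1)
  fwd <- compute_fcr(ab, data.frame(control = "x", experimental = "y",
                                    group_label = "g"))
  bwd <- compute_fcr(ab, data.frame(control = "y", experimental = "x",
                                    group_label = "g"))
  expect_equal(fwd$fcr, 1 / bwd$fcr)
})

test_that("inclusion filter keeps the directional percentage rule and pair minimum", {
  rec <- data.frame(
    genus = "G", group_label = "g",
    control = paste0("c", 1:4), experimental = paste0("e", 1:4),
    con_pct = c(0.005, 0.005, 0.005, 0.005),
    exp_pct = c(0.004, 0.006, 0.005, 0.003),
    fcr = c(0.8, 1.2, 1.0, 0.6))
  # all percentages below 0.01 on the relevant side: genus excluded
  expect_equal(nrow(apply_inclusion_filter(rec)), 0)
  # exactly three qualifying pairs: retained
  rec3 <- data.frame(
    genus = "G", group_label = "g",
    control = paste0("c", 1:4), experimental = paste0("e", 1:4),
    con_pct = c(0.5, 0.5, 0.5, 0.005),
    exp_pct = c(1.0, 0.8, 0.02, 0.004),
    fcr = c(2, 1.6, 0.04, 0.8))
  kept <- apply_inclusion_filter(rec3)
  expect_equal(nrow(kept), 3)
  # mixed directions with only two qualifying pairs: excluded
  rec2 <- rec3[c(1, 3), ]
  expect_equal(nrow(apply_inclusion_filter(rec2)), 0)
  # increased abundance qualifies on the experimental side only
  inc <- data.frame(genus = "G", group_label = "g", control = "c",
                    experimental = "e", con_pct = 0.001, exp_pct = 0.02,
                    fcr = 20)
  expect_equal(nrow(apply_inclusion_filter(inc, min_pairs = 1)), 1)
})

test_that("Z-statistic matches its closed form and handles the tails", {
  null <- z_statistic(c(1, 1, 1, 1) + c(0, 0, 1e-12, -1e-12))
  expect_equal(null$z, 0, tolerance = 1e-3)
  expect_equal(null$p, 0.5, tolerance = 1e-3)
  # constructed values: z = (mean-1)/(sd/sqrt(n)) exactly
  x <- c(2.01, 1.99, 2.02, 1.98)
  zs <- z_statistic(x)
  expect_equal(zs$z, (mean(x) - 1) / (sd(x) / 2))
  expect_lt(zs$p, 0.001)
  expect_equal(zs$direction, "stimulated")
  # population-sd variant
  zsd <- z_statistic(x, denominator = "sd")
  expect_equal(zsd$z, (mean(x) - 1) / sd(x))
  # suppression direction
  expect_equal(z_statistic(c(0.5, 0.4, 0.45))$direction, "suppressed")
  # large z (beyond the naive |z| = 8 regime): p finite and positive
  big <- z_statistic(c(2, 1.8, 2.2, 2.0))
  expect_gt(big$z, 8)
  expect_gt(big$p, 0)
  expect_lt(big$p, 1e-20)
  # extreme z: the log-scale tail stays finite even where p underflows
  extreme <- z_statistic(c(2, 2.0001, 1.9999, 2))
  expect_gt(extreme$z, 1000)
  expect_true(is.finite(extreme$neg_log10_p))
  expect_gt(extreme$neg_log10_p, 100)
  # degenerate variance flagged, p omitted
  deg <- z_statistic(c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(z_statistic(c(1, 2)), "at least 3")
})

test_that("Z-statistic is invariant under pair permutation", {
  set.seed(99)
  x <- rlnorm(8, 0.3, 0.4)
  a <- z_statistic(x)
  b <- z_statistic(sample(x))
  expect_equal(a$z, b$z)
  expect_equal(a$p, b$p)
})

test_that("volcano table tiers and coordinates are consistent", {
  rec <- data.frame(
    genus = rep(paste0("g", 1:4), each = 3),
    group_label = "g",
    control = "c", experimental = "e",
    con_pct = 1, exp_pct = 1,
    fcr = c(2.0, 2.1, 1.9,      # strongly stimulated
            1.0, 1.0, 1.0001,   # null
            0.52, 0.5, 0.48,    # strongly suppressed
            1.15, 0.9, 1.05))   # weak
  res <- differential_test(rec)
  v <- volcano_table(res)
  expect_equal(v$tier[v$genus == "g1"], "strong")
  expect_equal(v$log2_mean_fcr[v$genus == "g2"],
               log2(mean(c(1, 1, 1.0001))))
  expect_lt(abs(v$log2_mean_fcr[v$genus == "g2"]), 1e-4)
  # ordering by p matches ordering by |z|
  ok <- !res$degenerate
  expect_equal(order(res$p[ok]), order(-abs(res$z[ok])))
  # boundary tier: p exactly at 0.001 is "strong"
  res2 <- res[1, , drop = FALSE]
  res2$p <- 0.001
  expect_equal(volcano_table(res2)$tier, "strong")
  res2$p <- 0.04; expect_equal(volcano_table(res2)$tier, "significant")
  res2$p <- 0.2; expect_equal(volcano_table(res2)$tier, "ns")
})

test_that("concordance labels similar and opposite responses", {
  a <- data.frame(genus = c("g1", "g2", "g3", "g4"),
                  group_label = "a", n = 3, mean_fcr = c(2, 2, 0.5, 2),
                  sd_fcr = 0.1, z = 5,
                  p = c(0.01, 0.01, 0.01, 0.5),
                  direction = c("stimulated", "stimulated", "suppressed",
                                "stimulated"),
                  degenerate = FALSE)
  b <- data.frame(genus = c("g1", "g2", "g3", "g4"),
                  group_label = "b", n = 3, mean_fcr = c(2, 0.5, 0.4, 2),
                  sd_fcr = 0.1, z = 5,
                  p = c(0.01, 0.01, 0.01, 0.01),
                  direction = c("stimulated", "suppressed", "suppressed",
                                "stimulated"),
                  degenerate = FALSE)
  cc <- concordance(a, b)
  expect_equal(cc$label[cc$genus == "g1"], "similar")
  expect_equal(cc$label[cc$genus == "g2"], "opposite")
  expect_equal(cc$label[cc$genus == "g3"], "similar")
  expect_equal(cc$label[cc$genus == "g4"], "none")  # significant only in b
})

test_that("overlap summary reproduces the expected-by-chance arithmetic", {
  u <- paste0("g", 1:500)
  expect_equal(overlap_summary(u[1:10], u[11:20], u)$observed, 0)
  full <- overlap_summary(u, u, u)
  expect_equal(full$observed, 500)
  expect_equal(full$expected, 500)
  # 13 inhibited in vitro vs 46.2% of the universe inhibited in vivo:
  # expected overlap 13 x 0.462 = 6.0
  b <- u[1:231]  # 46.2% of 500
  ov <- overlap_summary(u[251:263], b, u)
  expect_equal(ov$expected, 13 * 0.462, tolerance = 1e-9)
  expect_lte(ov$observed, min(ov$n_a, ov$n_b))
  expect_error(overlap_summary("x", "y", character(0)), "empty universe")
  expect_error(overlap_summary("zzz", u[1], u), "subsets")
})
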