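test_that("summarize_pool matches hand-computed statistics", {
  props <- peptide_properties(c("KK", "DD", "LL"))
  s <- summarize_pool(props)
  expect_identical(s$N, 3L)
  expect_equal(s$mean[["boman"]], mean(c(5.55, 8.72, -4.92)), tolerance = 1e-9)
  expect_equal(s$sd[["boman"]], sd(c(5.55, 8.72, -4.92)), tolerance = 1e-9)
  expect_equal(s$fractions[["boman_high"]] + s$fractions[["boman_low"]], 1)
  # a pool of identical peptides has zero spread
  s0 <- summarize_pool(peptide_properties(rep("KAD", 4)))
  expect_true(all(s0$sd == 0))
  expect_error(summarize_pool(props[0, ]), "empty pool")
  expect_error(summarize_pool(props, isoform = "NfH"), "no isoform column")
})

test_that("summarize_pool ignores input order", {
  props <- peptide_properties(c("KADY", "LLMW", "GGSS", "RRHE"))
  a <- summarize_pool(props)
  b <- summarize_pool(props[sample(4), ])
  expect_equal(a$mean, b$mean)
  expect_equal(a$fractions, b$fractions)
})

test_that("compare_pools: Welch t for 2 groups, ANOVA F for 3+", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 2.1, 2.9, 4.2)
  same <- compare_pools(list(a = x, b = x))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand-checked 3-group one-way ANOVA (textbook closed form)
  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4); g3 <- c(6, 7, 8)
  res <- compare_pools(list(g1 = g1, g2 = g2, g3 = g3))
  grand <- mean(c(g1, g2, g3))
  ss_b <- 3 * sum((c(mean(g1), mean(g2), mean(g3)) - grand)^2)
  ss_w <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) + sum((g3 - mean(g3))^2)
  f_hand <- (ss_b / 2) / (ss_w / 6)
  expect_equal(res$kind, "F")
  expect_equal(res$statistic, f_hand, tolerance = 1e-9)
  expect_equal(res$p_value, stats::pf(f_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # Welch t equals its closed form
  tw <- compare_pools(list(a = x, b = y + 1))
  t_hand <- (mean(x) - mean(y + 1)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(tw$kind, "t")
  expect_equal(tw$statistic, t_hand, tolerance = 1e-9)
  expect_error(compare_pools(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("a known shift between synthetic pools is recovered", {
  set.seed(101)
  a <- rnorm(500, mean = 0, sd = 1)
  b <- rnorm(500, mean = 0.5, sd = 1)
  res <- compare_pools(list(a = a, b = b))
  # expected t approx -shift / sqrt(2/n) = -7.9; allow sampling error
  expect_lt(res$statistic, -4)
  expect_gt(res$statistic, -12)
  expect_lt(res$p_value, 1e-4)
})

test_that("site-count regression matches closed-form least squares", {
  rs <- load_rules()
  recs <- list(protein_record("a", strrep("GASK", 5)),
               protein_record("b", strrep("GASK", 10)),
               protein_record("c", strrep("GASK", 15)),
               protein_record("d", paste0(strrep("GASK", 8), "WWWW")))
  sms <- lapply(recs, find_sites, rs)
  fit <- sites_vs_length_regression(recs, sms)
  L <- vapply(recs, `[[`, 0L, "length")
  x <- vapply(sms, `[[`, 0L, "x")
  slope_hand <- sum((L - mean(L)) * (x - mean(x))) / sum((L - mean(L))^2)
  r2_hand <- cor(L, x)^2
  expect_equal(fit$slope, slope_hand, tolerance = 1e-9)
  expect_equal(fit$r_squared, r2_hand, tolerance = 1e-9)
  # perfectly collinear points give R^2 = 1
  sms3 <- sms[1:3]
  fit3 <- sites_vs_length_regression(recs[1:3], sms3)
  expect_equal(round(fit3$r_squared, 3), 1)
  expect_error(
    sites_vs_length_regression(rep(recs[1], 3), rep(sms[1], 3)),
    "degenerate")
})

test_that("aggregation flagging is the stated conjunction", {
  # engineered pool: two qualifying peptides (His-buffered, aliphatic,
  # stable), plus single-criterion failures: DDDDGGGG (high Boman, acidic),
  # IIIIVVVV (pI outside the window), GGGGGGGG (unstable, non-aliphatic)
  qualifying <- c("SHGIISVIGH", "IHAAGLHVLL")
  props <- peptide_properties(c(qualifying, "DDDDGGGG", "IIIIVVVV", "GGGGGGGG"))
  flagged <- flag_aggregation_prone(props, ph_window = c(6.6, 7.9))
  expect_setequal(flagged$sequence, qualifying)
  # each flagged row satisfies all four conditions
  expect_true(all(flagged$instability < 40 & flagged$aliphatic > 70 &
                    flagged$boman < 2.48 &
                    flagged$pI >= 6.6 & flagged$pI <= 7.9))
  # widening the pH window never shrinks the flagged set
  wider <- flag_aggregation_prone(props, ph_window = c(5, 10))
  expect_true(all(flagged$sequence %in% wider$sequence))
  expect_gte(nrow(wider), nrow(flagged))
})

test_that("APR classification delegates to the registered classifier", {
  on.exit(set_apr_classifier(NULL))
  set_apr_classifier(NULL)
  expect_error(classify_apr("AAA"), "no classifier configured")
  seqs <- c("VVIAAA", "GGGSSS", "KVVVVK")
  set_apr_classifier(function(s) rep(TRUE, length(s)))
  expect_true(all(classify_apr(seqs)))
  set_apr_classifier(function(s) rep(FALSE, length(s)))
  expect_false(any(classify_apr(seqs)))
  # regex classifier counts match a direct recount
  set_apr_classifier(function(s) grepl("VVV", s))
  expect_identical(sum(classify_apr(seqs)), sum(grepl("VVV", seqs)))
  set_apr_classifier(function(s) "not logical")
  expect_error(classify_apr(seqs), "logical")
})
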