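random_table <- function(levels, n_rep = 2, seed = 1, lambda = 20) {
  set.seed(seed)
  g <- do.call(tidyr::expand_grid, c(levels,
                                     list(replicate = seq_len(n_rep))))
  g$n_fp <- stats::rpois(nrow(g), lambda)
  g
}

test_that("log10(N + 1) transform behaves at its anchor points", {
  expect_equal(log_fp_transform(0), 0)
  expect_equal(log_fp_transform(9), 1)
  expect_equal(log_fp_transform(36621), 4.56374, tolerance = 1e-5)
  expect_error(log_fp_transform(-1), "non-negative")
})

test_that("term sums of squares match the aov projection oracle", {
  designs <- list(
    list(A = letters[1:2], B = c("x", "y")),
    list(A = letters[1:3], B = c("x", "y"), C = c("u", "v", "w")),
    list(A = letters[1:2], B = c("x", "y"), C = c("u", "v")))
  for (i in seq_along(designs)) {
    d <- random_table(designs[[i]], seed = 40 + i)
    mine <- balanced_factorial_anova(d)
    oracle <- aov_oracle(d)
    for (t in names(oracle$terms))
      expect_lt(abs(mine$terms$ss[mine$terms$term == t] -
                      unname(oracle$terms[t])), 1e-10)
    expect_lt(abs(mine$residual$ss - oracle$residual), 1e-10)
    expect_lt(abs(mine$stratum$ss - oracle$stratum), 1e-10)
  }
})

test_that("sums of squares are additive and percentages normalise", {
  d <- random_table(list(A = 1:3, B = 1:2, C = 1:2), n_rep = 3, seed = 50)
  an <- balanced_factorial_anova(d)
  expect_equal(an$stratum$ss + sum(an$terms$ss) + an$residual$ss,
               an$total_ss, tolerance = 1e-9 * an$total_ss)
  pct <- percent_ss(an)
  expect_equal(sum(pct$pct_ss), 100, tolerance = 1e-9)
  pct2 <- percent_ss(an, include_stratum = FALSE)
  expect_equal(sum(pct2$pct_ss), 100, tolerance = 1e-9)
})

test_that("constant responses put zero SS everywhere", {
  d <- random_table(list(A = 1:2, B = 1:2), seed = 51)
  d$n_fp <- 7L
  an <- balanced_factorial_anova(d)
  expect_true(all(abs(an$terms$ss) < 1e-12))
  expect_lt(abs(an$residual$ss), 1e-12)
  expect_error(percent_ss(an), "zero total")
})

test_that("the published design shape gives residual df 575 and stratum df 1", {
  full <- reference_design(replicates = 2)
  set.seed(52)
  full$n_fp <- stats::rpois(nrow(full), 10)
  an <- balanced_factorial_anova(full)
  expect_equal(an$residual$df, 575)
  expect_equal(an$stratum$df, 1)
  expect_equal(an$n_obs, 1152)
  expect_equal(sum(an$terms$df), 575) # treatments mirror the residual
})

test_that("unbalanced or incomplete tables are refused with the missing cells named", {
  d <- random_table(list(A = 1:2, B = 1:2), seed = 53)
  expect_error(balanced_factorial_anova(d[-1, ]), "missing cell")
  dup <- dplyr::bind_rows(d, d[1, ])
  expect_error(balanced_factorial_anova(dup), "balanced")
})

test_that("permutation probabilities are deterministic, bounded and saturate for strong effects", {
  # B needs enough levels that the within-stratum permutation group is
  # fine-grained enough to reach the minimum attainable p
  d <- random_table(list(A = 1:2, B = 1:6), seed = 54)
  d$n_fp <- ifelse(d$A == 1, 1000L, 0L) + stats::rpois(nrow(d), 3)
  an <- balanced_factorial_anova(d)
  p1 <- permutation_test(an, n_perm = 199, seed = 9)
  p2 <- permutation_test(an, n_perm = 199, seed = 9)
  expect_identical(p1$terms$perm_prob, p2$terms$perm_prob)
  expect_true(all(p1$terms$perm_prob >= 1 / 200))
  expect_true(all(p1$terms$perm_prob <= 1))
  expect_equal(p1$terms$perm_prob[p1$terms$term == "A"], 1 / 200)
  p3 <- permutation_test(an, n_perm = 199, seed = 10,
                         scheme = "whole_table")
  expect_equal(p3$terms$perm_prob[p3$terms$term == "A"], 1 / 200)
})

test_that("permutation test holds its nominal type-I error under the null", {
  lev <- list(A = 1:2, B = 1:2)
  n_sim <- 200
  reject <- 0
  for (s in seq_len(n_sim)) {
    d <- random_table(lev, seed = 1000 + s, lambda = 15)
    an <- balanced_factorial_anova(d)
    p <- permutation_test(an, n_perm = 99, seed = s)
    reject <- reject + (p$terms$perm_prob[p$terms$term == "A"] <= 0.05)
  }
  rate <- reject / n_sim
  # binomial(200, 0.05): central 99.9% interval is about [0.005, 0.105]
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.105)
})

test_that("cell means carry the sed of a balanced difference", {
  full <- reference_design(replicates = 2)
  set.seed(55)
  full$n_fp <- stats::rpois(nrow(full), 8)
  an <- balanced_factorial_anova(full)
  cm <- cell_means_sed(full, c("mapper", "stringency"), anova = an)
  expect_equal(cm$m, 288)
  expect_equal(cm$sed, sqrt(2 * an$residual$ms / 288))
  expect_equal(nrow(cm$means), 4)
  # hand-check one cell mean
  sub <- full[full$mapper == "BWA" & full$stringency == "strict", ]
  expect_equal(cm$means$mean[cm$means$mapper == "BWA" &
                               cm$means$stringency == "strict"],
               mean(log_fp_transform(sub$n_fp)))
  # selecting the full design leaves one observation per cell: undefined sed
  expect_error(
    cell_means_sed(full, c("length", "assembly", "mapper", "stringency",
                           "mapq", "caller", "depth_filter", "replicate"),
                   anova = an),
    "undefined|equally")
  # all-zero responses give all-zero cell means
  z <- full
  z$n_fp <- 0L
  zm <- suppressWarnings(cell_means_sed(z, "mapper",
                                        anova = balanced_factorial_anova(z)))
  expect_true(all(zm$means$mean == 0))
})

test_that("published seds derive from the residual row at 5 decimal places", {
  expect_equal(round(sed_from_residual(1.10452, 575, 8), 5), 0.02191)
  expect_equal(round(sed_from_residual(1.10452, 575, 288), 5), 0.00365)
  expect_equal(round(sed_from_residual(1.10452, 575, 192), 5), 0.00447)
  expect_equal(round(sed_from_residual(1.10452, 575, 96), 5), 0.00633)
})

test_that("zero-FP combinations require zero in every replicate", {
  d <- random_table(list(A = 1:4, B = 1:2), seed = 56)
  d$n_fp <- 0L
  z <- zero_fp_summary(d)
  expect_equal(z$n_combinations, 8)
  expect_equal(z$n_zero_fp, 8)
  # three combinations all-zero, one zero in a single replicate only
  d2 <- random_table(list(A = 1:4, B = 1:2), seed = 57, lambda = 5)
  d2$n_fp <- pmax(d2$n_fp, 1L)
  pick <- function(a, b) d2$A == a & d2$B == b
  d2$n_fp[pick(1, 1)] <- 0L
  d2$n_fp[pick(2, 1)] <- 0L
  d2$n_fp[pick(3, 2)] <- 0L
  d2$n_fp[pick(4, 2) & d2$replicate == 1] <- 0L
  z2 <- zero_fp_summary(d2, by = "A")
  expect_equal(z2$n_zero_fp, 3)
  expect_equal(z2$by_level$n_zero_fp[z2$by_level$A == 4], 0)
})

test_that("count tables round-trip through TSV", {
  d <- random_table(list(A = letters[1:2], B = 1:2), seed = 58)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fp_count_table(d, path)
  back <- read_fp_count_table(path)
  expect_equal(as.data.frame(back), as.data.frame(d))
  expect_error(read_fp_count_table("/nonexistent/file.tsv"), "no such file")
})

test_that("tidy and glance expose the conventional table layout", {
  d <- random_table(list(A = 1:2, B = 1:3), seed = 59)
  an <- permutation_test(balanced_factorial_anova(d), n_perm = 49, seed = 1)
  td <- tidy(an)
  expect_equal(td$term[1], "Replicate stratum")
  expect_equal(td$term[nrow(td)], "Residual")
  expect_true(all(c("df", "ss", "ms", "vr", "f_prob", "perm_prob",
                    "pct_ss") %in% names(td)))
  expect_equal(sum(td$pct_ss), 100, tolerance = 1e-9)
  gl <- glance(an)
  expect_equal(gl$n_obs, nrow(d))
  expect_equal(gl$residual_df, an$residual$df)
})
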