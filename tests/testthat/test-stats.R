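# Normality testing, split-plot ANOVA, pairwise comparisons.

test_that("Shapiro-Wilk wrapper enforces its preconditions", {
  q <- stats::qnorm(stats::ppoints(20))
  res <- shapiro_wilk(q)
  expect_gt(res$w, 0.99)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
  # heavy skew is detected in most replicates
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    shapiro_wilk(exp(stats::rnorm(50)))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("pooled unpaired t-test matches hand calculation", {
  res <- unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -sqrt(3) / sqrt(2), tolerance = 1e-9)
  expect_equal(round(res$t, 4), -1.2247)
  expect_equal(res$df, 4)
  expect_equal(round(res$p, 4), 0.2879)
  same <- unpaired_t_test(c(5, 5, 5), c(5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(unpaired_t_test(c(1, 1), c(2, 2)), "undefined")
  # scale invariance
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(2.0, 4.4, 3.3)
  expect_equal(unpaired_t_test(a * 7, b * 7)$t, unpaired_t_test(a, b)$t,
               tolerance = 1e-12)
  expect_error(unpaired_t_test(1, c(1, 2)), "n >= 2")
})

test_that("Bonferroni adjustment caps and preserves order", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.4, 4), 1)
  expect_equal(bonferroni(c(0.2, 0.04), 1e9), c(1, 1))
  expect_equal(bonferroni(0.03), 0.03)   # m = 1 identity
  p <- c(0.001, 0.02, 0.4)
  expect_true(all(diff(bonferroni(p, 5)) >= 0))
  expect_true(all(bonferroni(p, 5) >= p))
  expect_error(bonferroni(0.5, 0), "m must be")
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
})

test_that("mixed ANOVA matches the aov split-plot oracle", {
  # hand-sized design first: 2 subjects per group
  df <- random_design(1, n_range = 2:2)
  mine <- mixed_anova(df)
  ref <- aov_oracle(df)
  for (f in names(ref)) expect_equal(mine[[f]], ref[[f]], tolerance = 1e-9)
  # random small balanced and unbalanced designs, including 3 groups/states
  for (s in 1:60) {
    df <- random_design(100 + s,
                        n_groups = sample(2:3, 1),
                        n_states = sample(2:3, 1))
    mine <- mixed_anova(df, pairwise = FALSE)
    ref <- aov_oracle(df)
    for (f in names(ref))
      expect_equal(mine[[f]], ref[[f]], tolerance = 1e-9)
  }
})

test_that("mixed ANOVA is location invariant and validates structure", {
  df <- random_design(7)
  a <- mixed_anova(df, pairwise = FALSE)
  df2 <- df
  df2$value <- df$value + 123.45
  b <- mixed_anova(df2, pairwise = FALSE)
  expect_equal(b$f_group, a$f_group, tolerance = 1e-9)
  expect_equal(b$f_state, a$f_state, tolerance = 1e-9)
  expect_equal(b$f_interaction, a$f_interaction, tolerance = 1e-9)
  # missing paired state names the subject
  broken <- df[!(df$subject == "s001" & df$state == "st2"), ]
  expect_error(mixed_anova(broken), "s001")
  # fewer than two subjects per group
  tiny <- random_design(3, n_range = 2:2)
  tiny <- tiny[tiny$subject != "s001", ]
  expect_error(mixed_anova(tiny), "2 subjects")
})

test_that("pairwise table covers the four cell comparisons with m = 4", {
  df <- study_design_sim(5, delta = 2)
  res <- mixed_anova(df)
  pw <- res$pairwise
  expect_equal(nrow(pw), 4)
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 4))
  expect_true(all(pw$p_adj >= pw$p_raw))
  expect_setequal(
    pw$comparison,
    c("FGR vs control @ normoxia", "FGR vs control @ hypoxia",
      "normoxia vs hypoxia @ control", "normoxia vs hypoxia @ FGR"))
})

test_that("null mixed designs reject at close to the nominal rate", {
  rej <- matrix(NA, 600, 3)
  for (s in seq_len(nrow(rej))) {
    a <- mixed_anova(study_design_sim(s), pairwise = FALSE)
    rej[s, ] <- c(a$p_group, a$p_state, a$p_interaction) < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(abs(rates - 0.05) < 0.03))   # ~3 binomial SDs at 600 reps
})
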