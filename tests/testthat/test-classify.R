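test_that("index vectors map onto the four-group taxonomy", {
  # group A cohort means sit on the regular side of every cutoff
  a <- classify_trace(list(sd_x = 0.069, sd_v = 0.053, a1 = 0.178, mud_mdd = 0.242))
  expect_equal(a$group, "A")
  expect_false(a$drift_present)

  # irregular amplitude + period + drift
  d <- classify_trace(list(sd_x = 0.251, sd_v = 0.095, a1 = 0.08, mud_mdd = 0.793))
  expect_equal(d$group, "D")
  expect_true(d$drift_present)

  b <- classify_trace(list(sd_x = 0.07, sd_v = 0.03, a1 = 0.08, mud_mdd = 0.23))
  expect_equal(b$group, "B")
  c_ <- classify_trace(list(sd_x = 0.2, sd_v = 0.09, a1 = 0.2, mud_mdd = 0.45))
  expect_equal(c_$group, "C")
})

test_that("boundary values classify as regular and the A1 direction is inverted", {
  at_cut <- classify_trace(list(sd_x = 0.11, sd_v = 0.062, a1 = 0.117, mud_mdd = 0.349))
  expect_equal(at_cut$group, "A") # inclusive toward regular on every axis
  expect_false(at_cut$drift_present)

  # higher A1 = more regular: dropping A1 below the cutoff flips A -> B
  low_a1 <- classify_trace(list(sd_x = 0.05, sd_v = 0.03, a1 = 0.1, mud_mdd = 0.2))
  expect_equal(low_a1$group, "B")

  expect_error(
    classify_trace(list(sd_x = NA_real_, sd_v = 1, a1 = 1, mud_mdd = 1)),
    class = "respstab_input_error"
  )
})

test_that("the sd_v requirement only enters under the combined amplitude rule", {
  idx <- list(sd_x = 0.05, sd_v = 0.2, a1 = 0.2, mud_mdd = 0.2)
  expect_equal(classify_trace(idx)$group, "A")
  both <- default_cutoffs(amp_rule = "both")
  expect_equal(classify_trace(idx, cutoffs = both)$group, "C")
})

test_that("ROC analysis matches hand-derivable cases", {
  perfect <- roc_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$cutoff, 0.5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  ties <- roc_cutoff(rep(1, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(ties$auc, 0.5)

  # brute force over the 4 positive-negative pairs: 3 concordant
  mixed <- roc_cutoff(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(mixed$auc, 0.75)
  expect_equal(mixed$auc, auc_bruteforce(c(1, 2, 3, 4), c(0, 1, 0, 1)))

  expect_error(roc_cutoff(1:4, c(1, 1, 1, 1)), class = "respstab_input_error")
})

test_that("ROC AUC equals brute-force pair counting on random fixtures", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(rnorm(n, mean = labels), 1) # rounding forces ties
    got <- roc_cutoff(scores, labels)
    bf <- auc_bruteforce(scores, labels)
    expect_equal(got$auc, max(bf, 1 - bf), tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, plogis(scores))
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
    direction = "<", quiet = TRUE
  )))
  got <- roc_cutoff(scores, labels)
  expect_equal(if (got$flipped) 1 - got$auc else got$auc, ref, tolerance = 1e-12)
})

test_that("reversed score orientation is flipped and flagged", {
  r <- roc_cutoff(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))
  expect_true(r$flipped)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
})

test_that("one-way ANOVA reproduces the hand-computed F and textbook identities", {
  res <- anova_scheffe(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(res$f_statistic, 13.5, tolerance = 1e-10)
  expect_equal(res$f_statistic,
    anova_f_oracle(list(c(1, 2, 3), c(4, 5, 6))),
    tolerance = 1e-10
  )
  expect_equal(res$df, c(1L, 4L))
  expect_equal(res$subsets, "g1 < g2")

  expect_error(
    anova_scheffe(list(g1 = c(1, 1), g2 = c(1, 1))),
    class = "respstab_analysis_error"
  )
  expect_error(anova_scheffe(list(g1 = c(1, 2))), class = "respstab_input_error")
})

test_that("Scheffe subsets reproduce a two-block pattern", {
  set.seed(5)
  df <- data.frame(
    g = rep(c("A", "B", "C", "D"), each = 20),
    y = rnorm(80, mean = rep(c(0, 0, 2, 2), each = 20), sd = 0.3)
  )
  res <- anova_scheffe(df, y, g)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$subsets, "A, B < C, D")
  # all four cross-block pairs differ; the within-block pairs do not
  cross <- xor(res$pairwise$group1 %in% c("A", "B"), res$pairwise$group2 %in% c("A", "B"))
  expect_true(all(res$pairwise$significant[cross]))
  expect_false(any(res$pairwise$significant[!cross]))
})

test_that("cohort_report summarizes, tests and recovers on a small cohort", {
  # A vs C separates on the amplitude axis, which is robust at short
  # durations (A1's normalization presumes 20-min records)
  traces <- generate_cohort(5,
    groups = c("A", "C"), drift = c(FALSE, TRUE),
    seed = 300, duration = 300
  )
  rep <- suppressWarnings(cohort_report(traces))
  expect_equal(nrow(rep$per_trace), 10L)
  expect_true(all(c("group", "true_group", "sd_x") %in% names(rep$per_trace)))
  expect_gte(rep$accuracy, 0.8)
  expect_true(all(c("sd_x", "sd_v", "a1", "mud_mdd") %in% rep$anova$index))
  expect_gt(rep$roc$auc[rep$roc$index == "sd_x"], 0.9)

  single <- cohort_report(traces[1])
  expect_equal(nrow(single$per_trace), 1L)
})
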