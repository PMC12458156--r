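test_that("signed-rank test matches sign-pattern enumeration and the stats oracle", {
  ## 5 strictly positive differences: exact two-sided p = 2/32
  t5 <- wilcoxon_signed_rank(c(0.3, 1.2, 0.7, 2.2, 0.5))
  expect_equal(t5$p, 0.0625)
  expect_equal(t5$W, 15)
  ## antisymmetric differences: W at the null center, p ~ 1
  ta <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))
  expect_equal(ta$W, 10.5)
  expect_gt(ta$p, 0.95)
  ## random cases vs literal enumeration of all 2^N sign assignments
  set.seed(21)
  for (n in c(6, 8, 10)) {
    for (rep in 1:4) {
      d <- round(rnorm(n), 3)
      while (any(d == 0) || any(duplicated(abs(d)))) d <- round(rnorm(n), 3)
      expect_equal(wilcoxon_signed_rank(d)$p, oracle_wsr_p(d), tolerance = 1e-12)
      ## independent implementation cross-check
      expect_equal(wilcoxon_signed_rank(d)$p,
                   stats::wilcox.test(d, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
  ## zero differences dropped; all-zero gives the no-information result
  tz <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(tz$n_dropped, 2L)
  expect_equal(tz$n, 3L)
  nothing <- wilcoxon_signed_rank(rep(0, 4))
  expect_true(nothing$no_information)
  expect_true(is.na(nothing$p))
})

test_that("exact and normal-approximation p-values agree closely for N 10-15", {
  set.seed(22)
  for (rep in 1:40) {
    n <- sample(10:15, 1)
    d <- round(rnorm(n), 3)
    while (any(d == 0) || any(duplicated(abs(d)))) d <- round(rnorm(n), 3)
    t_ex <- wilcoxon_signed_rank(d)
    expect_equal(t_ex$method, "exact")
    p_approx <- 2 * pnorm(-abs(t_ex$z))
    expect_lt(abs(t_ex$p - p_approx), 0.02)
  }
})

test_that("effect sizes report both the z/N and z/sqrt(N) conventions", {
  es <- effect_size(2, 16)
  expect_equal(es$r_paper, 0.125)
  expect_equal(es$r_conventional, 0.5)
  expect_equal(effect_size(0, 9)$r_paper, 0)
  expect_equal(effect_size(0, 9)$r_conventional, 0)
  ## all-positive differences maximize the conventional effect for that N
  set.seed(23)
  n <- 8
  d_all_pos <- abs(rnorm(n)) + 0.01
  z_max <- wilcoxon_signed_rank(d_all_pos)$z
  for (rep in 1:20) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    if (all(signs > 0)) next
    z <- wilcoxon_signed_rank(d_all_pos * signs)$z
    expect_lte(z, z_max)
  }
})

test_that("BH adjustment reproduces the hand-executed step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(24)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  ## monotone in the sorted order
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("threshold success rates are exact fractions", {
  expect_equal(unname(threshold_success_rate(c(0.7, 0.5, 0.9), 0.6)), 2 / 3)
  expect_equal(unname(threshold_success_rate(c(0.7, 0.5, 0.9), 0)), 1)
  set.seed(25)
  v <- runif(50)
  ths <- c(0.2, 0.6, 0.8)
  got <- threshold_success_rate(v, ths)
  expect_equal(unname(got), vapply(ths, function(t) sum(v >= t) / 50, numeric(1)))
  expect_error(threshold_success_rate(c(0.5, 1.4), 0.5), "\\[0, 1\\]")
})

test_that("the comparison harness emits one test per competitor-dataset cell", {
  set.seed(26)
  df <- expand.grid(method = c("ours", paste0("rival", 1:5)),
                    dataset = paste0("ds", 1:6), micrograph = 1:8,
                    metric = c("precision", "recall"), stringsAsFactors = FALSE)
  df$value <- runif(nrow(df))
  rep_ <- compare_methods(df, "ours")
  expect_equal(sum(rep_$metric == "precision"), 30)   # 5 competitors x 6 datasets
  expect_equal(sum(rep_$metric == "recall"), 30)
  expect_true(all(rep_$p_adj >= rep_$p_raw, na.rm = TRUE))

  ## single competitor, single dataset: BH is the identity
  one <- df[df$method %in% c("ours", "rival1") & df$dataset == "ds1" &
            df$metric == "recall", ]
  r1 <- compare_methods(one, "ours")
  expect_equal(r1$p_adj, r1$p_raw)

  ## competitor identical to reference: no-information, not a p-value
  clone <- one
  v <- clone$value[clone$method == "ours"]
  clone$value[clone$method == "rival1"] <- v
  r2 <- compare_methods(clone, "ours")
  expect_true(r2$no_information)
  expect_true(is.na(r2$p_raw))

  ## misaligned micrographs rejected naming the dataset
  bad <- one[!(one$method == "rival1" & one$micrograph == 3), ]
  expect_error(compare_methods(bad, "ours"), "ds1")
})

test_that("false-discovery control holds across simulated null families", {
  ## under a global null, the chance that a BH-adjusted family reports any
  ## discovery at 0.05 stays near (at most about) 0.05
  set.seed(27)
  fam_hit <- replicate(300, {
    p <- vapply(1:10, function(i)
      wilcoxon_signed_rank(rnorm(20), rnorm(20))$p, numeric(1))
    any(bh_adjust(p) < 0.05)
  })
  expect_lte(mean(fam_hit), 0.07)
})
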