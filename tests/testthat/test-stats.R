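test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(41)
  x <- rnorm(8, 0, 1)
  y <- rnorm(10, 1, 1)
  av <- one_way_anova(c(x, y), rep(c("a", "b"), c(8, 10)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(av$f_stat, unname(tt$statistic)^2)
  expect_equal(av$p_value, tt$p.value)
  expect_equal(av$df_between, 1)
  expect_equal(av$df_within, 16)
})

test_that("degenerate ANOVA inputs are guarded", {
  av <- one_way_anova(rep(5, 12), rep(letters[1:3], each = 4))
  expect_equal(av$f_stat, 0)
  expect_equal(av$p_value, 1)
  expect_error(one_way_anova(rnorm(6), rep("a", 6)), "2 groups")
  expect_error(one_way_anova(rnorm(3), c("a", "b", "b")), "2 observations")
})

test_that("null ANOVA p-values are uniform", {
  set.seed(42)
  p <- replicate(500, {
    one_way_anova(rnorm(30), rep(letters[1:5], each = 6))$p_value
  })
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Tukey letters separate clear groups and unify identical ones", {
  set.seed(43)
  x <- c(rnorm(6, 0, 0.1), rnorm(6, 10, 0.1))
  g <- rep(c("g1", "g2"), each = 6)
  tk <- tukey_hsd(x, g)
  expect_lt(tk$pairwise_p[[1]], 1e-6)
  expect_equal(unname(tk$letters), c("a", "b"))

  # all groups drawn identically: a single shared letter
  same <- tukey_hsd(rep(c(2, 3), 9), rep(letters[1:3], each = 6))
  expect_equal(unname(same$letters), c("a", "a", "a"))

  # all-constant input: identical means are never declared different
  const <- tukey_hsd(rep(1, 12), rep(c("a", "b"), each = 6))
  expect_equal(unname(const$letters), c("a", "a"))

  expect_error(tukey_hsd(rnorm(6), rep("a", 6)), "2 groups")
  expect_error(tukey_hsd(rnorm(6), rep(c("a", "b"), 3), alpha = 1.5),
               "alpha")
})

test_that("Tukey pairwise p is no smaller than the unadjusted t-test p", {
  set.seed(44)
  for (i in 1:15) {
    k <- sample(3:6, 1)
    n <- sample(4:8, 1)
    x <- rnorm(k * n, rep(rnorm(k, 0, 1), each = n))
    g <- rep(paste0("g", seq_len(k)), each = n)
    tk <- tukey_hsd(x, g)
    pm <- tk$pairwise_p_matrix
    lev <- rownames(pm)
    for (a in seq_along(lev)) {
      for (b in seq_along(lev)) {
        if (b <= a) next
        # same pooled error term as the ANOVA for a fair comparison
        fit <- aov(x ~ g)
        mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
        df <- summary(fit)[[1]]["Residuals", "Df"]
        diffm <- mean(x[g == lev[a]]) - mean(x[g == lev[b]])
        se <- sqrt(mse * 2 / n)
        p_t <- 2 * pt(abs(diffm) / se, df, lower.tail = FALSE)
        expect_gte(pm[a, b] + 1e-12, p_t)
      }
    }
  }
})

test_that("compact letter display matches multcomp on a worked example", {
  skip_if_not_installed("multcomp")
  set.seed(45)
  x <- c(rnorm(6, 0), rnorm(6, 0.5), rnorm(6, 4), rnorm(6, 4.2), rnorm(6, 9))
  g <- factor(rep(paste0("t", 1:5), each = 6))
  tk <- tukey_hsd(x, g)
  fit <- stats::aov(x ~ g)
  cld <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(g = "Tukey")))
  same_sets <- function(lt) {
    lapply(seq_along(lt), function(i) {
      which(vapply(lt, function(o) {
        length(intersect(strsplit(o, "")[[1]], strsplit(lt[[i]], "")[[1]])) > 0
      }, logical(1)))
    })
  }
  # identical "shares a letter" relations, letter naming aside
  expect_equal(same_sets(unname(tk$letters[levels(g)])),
               same_sets(unname(cld$mcletters$Letters[levels(g)])))
})

test_that("compact letters satisfy their defining invariants on random data", {
  set.seed(46)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    n <- sample(3:8, 1)
    mu <- rnorm(k, 0, sample(c(0, 1, 3), 1))
    x <- rnorm(k * n, rep(mu, each = n))
    g <- rep(paste0("g", seq_len(k)), each = n)
    tk <- tukey_hsd(x, g)
    pm <- tk$pairwise_p_matrix
    lt <- tk$letters
    expect_true(all(nchar(lt) >= 1))
    share <- function(a, b) {
      length(intersect(strsplit(lt[[a]], "")[[1]],
                       strsplit(lt[[b]], "")[[1]])) > 0
    }
    for (a in rownames(pm)) {
      for (b in colnames(pm)) {
        if (a >= b) next
        if (pm[a, b] < tk$alpha) expect_false(share(a, b))
        else expect_true(share(a, b))
      }
    }
  }
})

test_that("pairwise-complete Pearson handles exact and missing cases", {
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  pt <- pearson_pairwise(d)
  expect_equal(pt$r, 1)
  expect_equal(pt$n, 10)

  d2 <- data.frame(x = 1:10, y = -(1:10))
  d2$y[4] <- NA
  pt2 <- pearson_pairwise(d2)
  expect_equal(pt2$r, -1)
  expect_equal(pt2$n, 9)

  # fewer than 3 complete pairs: cell reported missing
  d3 <- data.frame(x = c(1, 2, 3, 4), y = c(1, 2, NA, NA))
  pt3 <- pearson_pairwise(d3)
  expect_true(is.na(pt3$r))
  expect_equal(pt3$n, 2)

  # p-value agrees with cor.test
  set.seed(47)
  d4 <- data.frame(a = rnorm(20), b = rnorm(20))
  pt4 <- pearson_pairwise(d4)
  ref <- cor.test(d4$a, d4$b)
  expect_equal(pt4$r, unname(ref$estimate))
  expect_equal(pt4$p, ref$p.value)
})

test_that("Pearson estimate is unbiased for a known correlation", {
  set.seed(48)
  rho <- 0.7
  rhat <- replicate(300, {
    x <- rnorm(60)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(60)
    pearson_pairwise(data.frame(x, y))$r
  })
  expect_equal(mean(rhat), rho, tolerance = 0.02)
})

test_that("per-analyte ANOVA finds the treatment signal in synthetic data", {
  sim <- simulate_experiment(sim_config(seed = 9))
  out <- anova_by_analyte(sim$records, analytes = c("acetic_mM", "nh3_mM"),
                          times = 24)
  expect_equal(nrow(out$anova), 2)
  expect_true(all(out$anova$df_between == 9))
  expect_true(all(out$anova$p_value < 0.05))
  letters24 <- out$letters[out$letters$analyte == "nh3_mM", ]
  expect_equal(nrow(letters24), 10)
  # the strongest protein dose separates from the control
  ctl <- letters24$letters[letters24$treatment_id == "Control"]
  whey <- letters24$letters[letters24$treatment_id == "WHEY_high"]
  expect_equal(
    length(intersect(strsplit(ctl, "")[[1]], strsplit(whey, "")[[1]])), 0
  )
})
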