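test_that("distance codings agree with brute-force enumeration", {
  chans <- c("Fz", "Cz", "Pz", "POz")
  regs <- c("F", "C", "P", "O")
  for (s in chans) for (so in chans) for (r in regs) {
    ps <- match(s, chans); pso <- match(so, chans); pr <- match(r, regs)
    expect_equal(d_source_so(s, so), abs(ps - pso))
    expect_equal(d_sink_so(r, so), abs(pr - pso))
    expect_equal(d_source_sink(s, r), abs(pr - ps))
    expect_equal(relative_distance(r, s, so), abs(pr - pso) - abs(ps - pso))
  }
  # the worked example: SO at Cz, source Fz, sink O -> +1
  expect_equal(relative_distance("O", "Fz", "Cz"), 1)
  expect_equal(relative_distance("F", "Fz", "POz"), 0)
  expect_equal(relative_distance("F", "POz", "Fz"), -3)
  expect_error(channel_position("Oz"), "unknown")
  expect_error(region_position("X"), "unknown")
})

test_that("the mean +/- 2 SD outlier rule drops exactly the right values", {
  v <- c(rep(1, 9), 50)
  # mean 5.9, sd ~15.5: 50 lies above the upper bound
  out <- exclude_outliers(v)
  expect_equal(out$n_dropped, 1)
  expect_false(out$keep[10])
  # all-equal values: bounds collapse onto the value, nothing dropped
  out <- exclude_outliers(rep(3, 5))
  expect_equal(out$n_dropped, 0)
  # standard normal: about 4.6 % dropped
  set.seed(70)
  out <- exclude_outliers(rnorm(10000))
  expect_lt(abs(out$n_dropped / 10000 - 0.046), 0.007)
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("SO versus non-SO ANOVA flags planted phase effects", {
  set.seed(71)
  n <- 40
  mk <- function(eff) {
    do.call(rbind, lapply(seq_len(n), function(s) {
      mu <- c("-pi" = 0, "-pi/2" = eff, "0" = 0, "pi/2" = eff,
              "pi" = 0, "nonSO" = 0)
      data.frame(subject = s, condition = names(mu),
                 value = 1 + mu + rnorm(6, sd = 0.3) + rnorm(1, sd = 0.1))
    }))
  }
  res <- compare_so_vs_nonso(mk(1))
  expect_s3_class(res, "so_stats")
  p_at <- function(res, cond) {
    hit <- grepl(paste0("\\b", cond, "\\b"), res$comparisons$pair) |
      res$comparisons$pair == paste0("nonSO-", cond) |
      res$comparisons$pair == paste0(cond, "-nonSO")
    res$comparisons$p_adj[hit][1]
  }
  expect_lt(p_at(res, "pi/2"), 0.05)
  expect_gt(p_at(res, "0"), 0.05)
  # identical distributions: F near 1, nothing significant at trough
  res0 <- compare_so_vs_nonso(mk(0))
  expect_gt(res0$anova["p"], 0.001)
  expect_error(compare_so_vs_nonso(mk(1)[mk(1)$subject <= 2, ]), "3 subjects")
})

test_that("ANOVA type-I error is near nominal under the null", {
  set.seed(72)
  rej <- mean(replicate(400, {
    d <- data.frame(subject = rep(1:15, 6),
                    condition = rep(c("-pi", "-pi/2", "0", "pi/2", "pi",
                                      "nonSO"), each = 15),
                    value = rnorm(90))
    compare_so_vs_nonso(d, outliers = FALSE)$anova["p"] < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("the peak-height LME recovers a planted distance coefficient", {
  gen <- function(seed) {
    set.seed(seed)
    chans <- c("Fz", "Cz", "Pz", "POz")
    g <- expand.grid(subject = 1:40, source = chans, so_channel = chans,
                     phase_code = 1:2, stringsAsFactors = FALSE)
    g$d_source_so <- d_source_so(g$source, g$so_channel)
    g$source_idx <- channel_position(g$source)
    g$so_channel_idx <- channel_position(g$so_channel)
    off <- rnorm(40, sd = 0.3)
    g$peak_value <- 2 - 0.4 * g$d_source_so + off[g$subject] +
      rnorm(nrow(g), sd = 0.3)
    g
  }
  fit <- peak_height_lme(gen(1), c("source_idx", "so_channel_idx",
                                   "d_source_so", "phase_code"))
  co <- fit$coefficients
  b <- co$estimate[co$term == "d_source_so"]
  expect_lt(abs(b + 0.4), 0.1)
  expect_lt(co$p[co$term == "d_source_so"], 0.01)
  # a term with no planted effect keeps a null-ish p value distribution
  set.seed(2)
  p0 <- replicate(40, {
    g <- gen(sample.int(1e6, 1))
    f <- peak_height_lme(g, c("d_source_so", "phase_code"), outliers = FALSE)
    f$coefficients$p[f$coefficients$term == "phase_code"]
  })
  expect_lt(mean(p0 < 0.05), 0.2)
  one_subject <- gen(3)
  one_subject <- one_subject[one_subject$subject == 1, ]
  expect_error(peak_height_lme(one_subject, "d_source_so"), "subject")
})

test_that("LME with one observation per cell degenerates toward OLS", {
  set.seed(73)
  g <- data.frame(subject = rep(1:30, each = 4),
                  x = rep(0:3, 30))
  g$peak_value <- 1 + 0.5 * g$x + rnorm(nrow(g), sd = 0.2)
  fit <- peak_height_lme(g, "x", outliers = FALSE)
  ols <- coef(lm(peak_value ~ x, data = g))
  b <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_lt(abs(b - ols[["x"]]), 1e-4)
})

test_that("WPA regressions recover a planted dependence in the right group", {
  set.seed(74)
  n <- 40
  flow0 <- rnorm(n, mean = 1, sd = 0.3)      # group 0 drives behaviour
  beh <- data.frame(subject = 1:n,
                    improvement = 1 + 0.25 * scale(flow0)[, 1] +
                      rnorm(n, sd = 0.05))
  flow <- rbind(data.frame(subject = 1:n, group = 0, value = flow0),
                data.frame(subject = 1:n, group = 1,
                           value = 0.7 * flow0 + rnorm(n, sd = 0.25)),
                data.frame(subject = 1:n, group = 3,
                           value = rnorm(n, 1, 0.3)))
  res <- wpa_regressions(flow, beh)
  g0 <- res$groups[res$groups$group == 0, ]
  g3 <- res$groups[res$groups$group == 3, ]
  expect_gt(g0$r, 0.8)
  expect_lt(g0$p_adjusted, 0.01)
  expect_gt(g3$p_adjusted, 0.05)
  expect_gt(g0$r, res$groups$r[res$groups$group == 1])
  # perfectly collinear: r = 1, p at the floor
  fl <- data.frame(subject = 1:n, group = 9, value = beh$improvement)
  res2 <- wpa_regressions(fl, beh, outliers = FALSE)
  expect_equal(res2$groups$r, 1, tolerance = 1e-12)
  expect_lt(res2$groups$p_adjusted, 1e-12)
})

test_that("Bonferroni controls the family-wise error over the distance groups", {
  set.seed(75)
  fw <- mean(replicate(300, {
    n <- 20
    beh <- data.frame(subject = 1:n, improvement = rnorm(n, 1, 0.1))
    flow <- do.call(rbind, lapply(0:3, function(g)
      data.frame(subject = 1:n, group = g, value = rnorm(n))))
    res <- wpa_regressions(flow, beh, outliers = FALSE)
    any(res$groups$p_adjusted < 0.05)
  }))
  expect_lte(fw, 0.08)
})

test_that("p-value adjustments behave as Bonferroni and monotone BH", {
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_equal(p.adjust(p, "bonferroni"), pmin(1, 4 * p))
  bh <- p.adjust(p, "BH")
  expect_true(all(diff(bh[order(p)]) >= 0))
})
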