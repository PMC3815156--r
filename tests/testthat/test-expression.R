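test_that("mode normalization recovers planted scale factors", {
  set.seed(11)
  base <- matrix(rnbinom(500 * 6, mu = 200, size = 5), 500, 6,
                 dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:6)))
  nm <- mode_normalize(base)
  # identical-ish samples: all factors near a common scale, ratios near 1
  expect_true(all(nm$scale_factors > 0))

  doubled <- base
  doubled[, 3] <- base[, 3] * 2L
  nm2 <- mode_normalize(doubled)
  rel <- nm2$scale_factors[3] / median(nm2$scale_factors[-3])
  expect_lt(abs(rel - 2), 0.1)            # factor approx 2 (within 5%)

  # idempotence: re-normalizing normalized values gives factors near 1
  nm3 <- mode_normalize(nm2$values)
  expect_true(all(abs(nm3$scale_factors - 1) < 0.02))
})

test_that("mode normalization recovers scalings up to x8", {
  set.seed(12)
  base <- matrix(rnbinom(3000 * 5, mu = 300, size = 5), 3000, 5,
                 dimnames = list(sprintf("g%04d", 1:3000), paste0("s", 1:5)))
  for (f in c(2, 4, 8)) {
    m <- base
    m[, 2] <- base[, 2] * f
    nm <- mode_normalize(m)
    rel <- nm$scale_factors[2] / median(nm$scale_factors[-2])
    expect_lt(abs(rel / f - 1), 0.05)
  }
})

test_that("all-identical samples get equal factors and an all-zero sample errors", {
  m <- matrix(rep(c(10, 50, 200, 1000), 4), 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  nm <- mode_normalize(m)
  expect_equal(max(nm$scale_factors) / min(nm$scale_factors), 1,
               tolerance = 1e-9)
  m[, 2] <- 0
  expect_error(mode_normalize(m), "s2")
})

test_that("low-expression filter matches its brute-force oracle and boundaries", {
  groups <- rep(c("a", "b", "c", "d"), each = 3)
  m <- rbind(kept = c(20, 20, 20, rep(1, 9)),       # group a median 20 > 16
             dropped = rep(16, 12),                 # strictly-greater rule
             zero = rep(0, 12))
  colnames(m) <- paste0("s", 1:12)
  out <- filter_low_expression(m, groups)
  expect_identical(rownames(out), "kept")

  set.seed(21)
  r <- matrix(rnbinom(200 * 12, mu = 20, size = 1), 200, 12,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:12)))
  out <- filter_low_expression(r, groups)
  oracle <- rownames(r)[sapply(seq_len(nrow(r)), function(i) {
    any(tapply(r[i, ], groups, median) > 16)
  })]
  expect_identical(rownames(out), oracle)
})

test_that("DTK with two groups equals the Welch t-test", {
  set.seed(31)
  for (r in 1:50) {
    x <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    d <- dtk_pairwise(list(g1 = x, g2 = y))
    w <- t.test(x, y)
    expect_lt(abs(d$p - w$p.value), 1e-6)
    expect_lt(abs(d$df - unname(w$parameter)), 1e-6)
  }
})

test_that("DTK with equal n and variance matches Tukey HSD", {
  # equal sample variances by construction (shared residual vector), so the
  # per-pair standard errors match the pooled ones exactly and only the df
  # differ (Welch 2(n-1) vs pooled k(n-1)); at n = 30 the p-values agree
  set.seed(32)
  for (r in 1:20) {
    k <- 4; n <- 30
    resid <- scale(rnorm(n))[, 1]
    mns <- rnorm(k)
    vals <- unlist(lapply(mns, function(m) m + resid))
    grp <- factor(rep(paste0("g", 1:k), each = n))
    d <- dtk_pairwise(split(vals, grp))
    hsd <- TukeyHSD(aov(vals ~ grp))$grp
    key_d <- paste(pmin(d$group1, d$group2), pmax(d$group1, d$group2))
    key_h <- sapply(strsplit(rownames(hsd), "-"), function(p) {
      paste(pmin(p[1], p[2]), pmax(p[1], p[2]))
    })
    m <- match(key_d, key_h)
    expect_true(all(abs(d$p - hsd[m, "p adj"]) < 0.02))
  }
})

test_that("DTK handles degenerate and symmetric cases", {
  d <- dtk_pairwise(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_equal(d$p, 1)
  expect_equal(d$diff, 0)
  expect_true(d$ci_low <= 0 && 0 <= d$ci_high)
  d2 <- dtk_pairwise(list(a = c(1, 1, 1), b = c(2, 2, 2)))
  expect_equal(d2$p, 0)

  x <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  d3 <- dtk_pairwise(x)
  d4 <- dtk_pairwise(rev(x))
  for (i in seq_len(nrow(d3))) {
    j <- which((d4$group1 == d3$group1[i] & d4$group2 == d3$group2[i]) |
               (d4$group1 == d3$group2[i] & d4$group2 == d3$group1[i]))
    expect_equal(d3$p[i], d4$p[j], tolerance = 1e-12)
  }
  # p monotone decreasing in |diff| at fixed se/df: shift one group mean
  base <- list(a = c(0, 0.5, 1, 1.5), b = c(0, 0.5, 1, 1.5))
  ps <- sapply(c(0.5, 1, 2, 4), function(s) {
    dtk_pairwise(list(a = base$a, b = base$b + s))$p
  })
  expect_true(all(diff(ps) < 0))
  # CI always brackets the difference
  d5 <- dtk_pairwise(list(a = rnorm(6), b = rnorm(6, 2), c = rnorm(6)))
  expect_true(all(d5$ci_low <= d5$diff & d5$diff <= d5$ci_high))
})

test_that("group-specific caller applies the all-pairs rule and finds planted genes", {
  # rule: flag iff all target-vs-other p < alpha
  st <- small_study()
  co <- st$cohort
  filt <- filter_low_expression(co$counts, co$groups)
  nm <- mode_normalize(filt)
  calls <- call_group_specific(nm$values, co$groups, "HER2")
  expect_true(all(calls$is_DE == (calls$p_max < 0.05)))
  planted <- co$truth$gene
  sens <- mean(planted %in% calls$gene[calls$is_DE])
  expect_gte(sens, 0.9)
  # planted direction recovered
  dirs <- calls$direction[match(planted, calls$gene)]
  agree <- mean(dirs == co$truth$direction, na.rm = TRUE)
  expect_gte(agree, 0.85)
})

test_that("group-specific caller is conservative under the global null", {
  set.seed(41)
  groups <- rep(c("benign", "ER+", "TN", "HER2"), each = 6)
  m <- matrix(rnbinom(300 * 24, mu = 150, size = 4), 300, 24,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:24)))
  calls <- call_group_specific(m, groups, "HER2")
  expect_lte(mean(calls$is_DE), 0.05)
})
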