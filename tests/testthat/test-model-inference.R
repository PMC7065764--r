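test_that("standardizePredictors centres and scales with the n-1 sd", {
  X <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  Z <- standardizePredictors(X)
  expect_equal(Z$a, c(-1, 0, 1))
  expect_equal(unname(colMeans(as.matrix(Z))), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(as.matrix(Z), 2, sd)), c(1, 1), tolerance = 1e-12)
  # already standardized input is unchanged
  expect_equal(as.matrix(standardizePredictors(Z)), as.matrix(Z),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardizePredictors(data.frame(a = c(1, 1, 1))), "constant")
})

test_that("fitGaussian matches hand arithmetic and the ML conventions", {
  f <- fitGaussian(c(1, 2, 2, 4), data.frame(x = 1:4), "x")
  expect_equal(unname(f@coefficients), c(0, 0.9), tolerance = 1e-12)
  expect_equal(f@k, 3L)

  # intercept-only coefficient is the mean
  f0 <- fitGaussian(c(3, 5, 10), terms = character(0))
  expect_equal(unname(f0@coefficients), 6)

  # AIC/AICc follow the Gaussian ML bookkeeping; cross-check against
  # stats::AIC on the same lm fit
  set.seed(2)
  y <- rnorm(20); d <- data.frame(x = rnorm(20))
  f1 <- fitGaussian(y, d, "x")
  ref <- lm(y ~ x, data = d)
  expect_equal(f1@loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
  expect_equal(f1@aic, AIC(ref), tolerance = 1e-10)
  expect_equal(f1@aicc, f1@aic + 2 * 3 * 4 / (20 - 3 - 1), tolerance = 1e-10)
  expect_equal(f1@r2, summary(ref)$r.squared, tolerance = 1e-10)

  # perfect fit flagged with infinite likelihood
  fp <- fitGaussian(2 * (1:6) + 1, data.frame(x = 1:6), "x")
  expect_equal(fp@r2, 1)
  expect_identical(fp@aic, -Inf)

  # rank-deficient designs are refused, naming the aliased term
  dd <- data.frame(x = 1:5, xx = 1:5)
  expect_error(fitGaussian(rnorm(5), dd, c("x", "xx")), "alias")
})

test_that("fitGaussian coefficients agree with the normal-equations oracle", {
  for (seed in 1:20) {
    des <- randomDesign(n = sample(10:30, 1), p = sample(1:5, 1), seed = seed)
    f <- fitGaussian(des$y, des$X, des$terms)
    Xm <- cbind(1, as.matrix(des$X))
    beta <- solve(crossprod(Xm), crossprod(Xm, des$y))
    expect_equal(unname(f@coefficients), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("compareNestedByAIC prefers curvature only when it is real", {
  set.seed(9)
  x <- seq(-2, 2, length.out = 40)
  d <- data.frame(x = x, x_sq = x^2)
  # pure linear signal: the linear model wins
  yl <- 2 * x + rnorm(40, sd = 0.5)
  cl <- compareNestedByAIC(yl, d, "x", "x_sq")
  expect_equal(cl$chosen@terms, "x")
  # strong curvature: the quadratic wins
  yq <- x^2 + rnorm(40, sd = 0.1)
  cq <- compareNestedByAIC(yq, d, "x", "x_sq")
  expect_true("x_sq" %in% cq$chosen@terms)
  # identical term sets tie, and the tie goes to the smaller model
  ct <- compareNestedByAIC(yl, d, "x", character(0))
  expect_equal(ct$chosen@terms, "x")
  expect_equal(ct$chosen@k, ct$base@k)
})

test_that("screenCollinearity flags correlation and prunes by VIF", {
  set.seed(21)
  n <- 60
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  sc <- screenCollinearity(X)
  expect_equal(sort(sc$retained), c("a", "b", "c"))
  expect_true(all(sc$vif < 2))
  expect_equal(nrow(sc$correlationFlags), 0)

  # duplicated predictor: infinite VIF, exactly one of the pair removed
  Xd <- data.frame(a = rnorm(n), b = rnorm(n))
  Xd$c <- Xd$a
  scd <- screenCollinearity(Xd)
  expect_length(scd$removed, 1)
  expect_true(scd$removed %in% c("a", "c"))

  # near-duplicate (noise sd 10x smaller): VIF = 1/(1-r^2) > 5 for the pair
  Xn <- data.frame(x1 = rnorm(n))
  Xn$x2 <- Xn$x1 + rnorm(n, sd = sd(Xn$x1) / 10)
  Xn$z <- rnorm(n)
  r <- cor(Xn$x1, Xn$x2)
  expect_gt(1 / (1 - r^2), 5)
  scn <- screenCollinearity(Xn)
  expect_length(scn$removed, 1)
  expect_true(scn$removed %in% c("x1", "x2"))
  expect_true(nrow(scn$correlationFlags) >= 1)

  expect_error(screenCollinearity(data.frame(a = rep(1, 5), b = rnorm(5))),
               "constant")
})

test_that("allSubsets enumerates additive models with marginal quadratics", {
  set.seed(31)
  n <- 40
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- d$a + rnorm(n)
  ms <- allSubsets(y, d, c("a", "b"))
  expect_equal(nrow(modelTable(ms)), 4)       # 2^2 additive subsets
  expect_equal(sum(modelTable(ms)$weight), 1, tolerance = 1e-12)
  expect_equal(modelTable(ms)$delta[1], 0)

  # seven predictors -> 128 additive models
  d7 <- as.data.frame(matrix(rnorm(n * 7), n))
  names(d7) <- paste0("v", 1:7)
  ms7 <- allSubsets(rnorm(n), d7, names(d7))
  expect_equal(nrow(modelTable(ms7)), 128)

  # marginality: the squared term never appears without its linear term
  msq <- allSubsets(y, d, c("a", "b"), quadraticFor = "a")
  labs <- modelTable(msq)$model
  expect_equal(length(labs), 4 + 2)  # each a-containing subset gains a variant
  hasSq <- grepl("a_sq", labs)
  expect_true(all(grepl("(^| )a( |$)", sub(" \\+ a_sq", "", labs[hasSq]))))
})

test_that("confidenceSet keeps the delta <= 2 models and renormalizes", {
  set.seed(41)
  n <- 30
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 * d$a + rnorm(n, sd = 0.4)
  ms <- allSubsets(y, d, names(d))
  cs <- confidenceSet(ms, deltaMax = 2)
  expect_true(all(modelTable(cs)$delta <= 2 + 1e-12))
  expect_equal(sum(modelTable(cs)$weight), 1, tolerance = 1e-12)
  expect_gte(nrow(modelTable(cs)), 1)
  # rule application on a fabricated delta ladder via direct fits
  f1 <- fitGaussian(y, d, "a")
  expect_equal(modelTable(confidenceSet(ms, 0.001))$delta[1], 0)
})

test_that("averageModel does conditional averaging with unconditional SEs", {
  set.seed(51)
  n <- 25
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 3 * d$a + rnorm(n, sd = 0.2)
  # singleton confidence set: averaged output equals the single fit
  ms <- allSubsets(y, d, c("a", "b"))
  cs <- confidenceSet(ms, deltaMax = 0.5)
  if (nrow(modelTable(cs)) == 1) {
    av <- averageModel(cs)
    f <- modelFits(cs)[[1]]
    tab <- averagedTable(av)
    expect_equal(tab$estimate[tab$term == "a"],
                 unname(f@coefficients["a"]), tolerance = 1e-12)
    expect_equal(tab$se[tab$term == "a"], unname(f@se["a"]),
                 tolerance = 1e-12)
    expect_true(all(tab$ri == 1))
  }
  # weighted-mean identity on a constructed two-model set
  fits <- list(fitGaussian(y, d, "a"), fitGaussian(y, d, c("a", "b")))
  ms2 <- fragdep:::.rankFits(fits, "y")
  av2 <- averageModel(ms2)
  w <- modelTable(ms2)$weight
  bA <- vapply(modelFits(ms2), function(f) f@coefficients[["a"]], numeric(1))
  tab2 <- averagedTable(av2)
  expect_equal(tab2$estimate[tab2$term == "a"], sum(w * bA),
               tolerance = 1e-12)
  expect_equal(tab2$ri[tab2$term == "a"], 1)          # term in every model
  expect_lt(tab2$ri[tab2$term == "b"], 1)
  # CI is estimate +/- 1.96 se
  expect_equal(tab2$ci_upper - tab2$estimate, 1.96 * tab2$se,
               tolerance = 1e-12)
})

test_that("hierarchicalPartition decomposes R2 exactly", {
  # two orthogonal predictors: independent effects equal marginal R2,
  # joint effects vanish (brute-force over the 4 subset fits)
  x1 <- c(-1, -1, 1, 1); x2 <- c(-1, 1, -1, 1)
  y <- 2 * x1 + x2 + c(0.1, -0.1, -0.1, 0.1)
  d <- data.frame(x1 = x1, x2 = x2)
  hp <- hierarchicalPartition(y, d, c("x1", "x2"))
  r2of <- function(t) summary(lm(y ~ ., data = d[t]))$r.squared
  expect_equal(hp$independent[1], r2of("x1"), tolerance = 1e-10)
  expect_equal(hp$independent[2], r2of("x2"), tolerance = 1e-10)
  expect_equal(hp$joint, c(0, 0), tolerance = 1e-10)

  # single predictor: independent effect is the simple-regression R2
  hp1 <- hierarchicalPartition(y, d, "x1")
  expect_equal(hp1$independent, r2of("x1"), tolerance = 1e-12)

  # partition identity on random correlated designs up to p = 6
  for (seed in c(1, 2, 3)) {
    p <- c(3, 5, 6)[seed]
    des <- randomDesign(n = 25, p = p, seed = 100 + seed)
    hp2 <- hierarchicalPartition(des$y, des$X, des$terms)
    expect_equal(sum(hp2$independent), attr(hp2, "full_r2"),
                 tolerance = 1e-8)
    expect_equal(sum(hp2$independent_pct), 100, tolerance = 1e-8)
  }
})

test_that("selectBuffer picks the radius that explains the responses", {
  set.seed(61)
  n <- 30
  resp <- rnorm(n)
  cands <- list(r250 = rnorm(n),              # pure noise
                r1000 = resp)                 # identical to the response
  sel <- selectBuffer(list(y = resp), cands)
  expect_equal(sel$chosen, "r1000")
  expect_equal(nrow(sel$table), 2)            # responses x radii rows
  # a single candidate is chosen trivially
  expect_equal(selectBuffer(list(y = resp), cands["r250"])$chosen, "r250")
  expect_error(selectBuffer(list(y = resp), list(a = rnorm(n + 1))),
               "align")
})

test_that("refitExcluding reports the R2 change for declared outliers", {
  set.seed(71)
  n <- 25
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.3)
  y[1] <- 10                                  # planted contamination
  ids <- paste0("s", seq_len(n))
  d <- data.frame(x = x)
  out <- refitExcluding(y, d, "x", exclude = "s1", siteIDs = ids)
  expect_gt(out$delta_r2, 0)
  expect_equal(out$excluded, "s1")
  # excluding nothing returns identical fits
  same <- refitExcluding(y, d, "x", exclude = character(0), siteIDs = ids)
  expect_equal(same$delta_r2, 0)
  expect_equal(same$before@coefficients, same$after@coefficients)
  # removing almost everything is refused
  expect_error(refitExcluding(y, d, "x", exclude = ids[-(1:3)],
                              siteIDs = ids), "too few")
  expect_error(refitExcluding(y, d, "x", exclude = "nope", siteIDs = ids),
               "unknown")
})
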