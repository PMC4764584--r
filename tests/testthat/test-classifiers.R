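# Fisher scores, the LDA cascade, discretization, mutual information,
# K2 structure learning and leave-one-out cross-validation.

test_that("Fisher scores match the class-scatter formula", {
  set.seed(41)
  f <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1))
  cl <- rep(c("a", "b"), each = 50)
  X <- cbind(f1 = f, flat = rep(2, 100))
  s <- suppressWarnings(fisherScores(X, cl))
  # hand evaluation
  u <- mean(f)
  num <- 50 * (mean(f[1:50]) - u)^2 + 50 * (mean(f[51:100]) - u)^2
  den <- 50 * sd(f[1:50])^2 + 50 * sd(f[51:100])^2
  expect_equal(unname(s["f1"]), num / den)
  expect_equal(unname(s["flat"]), 0)      # no between-class scatter
  # affine invariance
  s2 <- suppressWarnings(fisherScores(cbind(f1 = 3 * f + 7, flat = rep(2, 100)), cl))
  expect_equal(unname(s2["f1"]), unname(s["f1"]), tolerance = 1e-12)
})

test_that("the LDA cascade separates well-separated classes perfectly", {
  set.seed(42)
  n <- 30
  mk <- function(mu) matrix(rnorm(n * 4, 0, 0.5), n, 4) +
    matrix(mu, n, 4, byrow = TRUE)
  X <- rbind(mk(c(10, 0, 0, 0)), mk(c(0, 10, 0, 0)), mk(c(0, 0, 10, 0)),
             mk(c(0, 0, 0, 10)))
  cl <- rep(c("hepatocyte", "SEC", "Kupffer", "stellate"), each = n)
  cascade <- c("hepatocyte", "SEC", "Kupffer", "stellate")
  res <- loocv(function(Xt, ct) ldaCascade(Xt, ct, k = 4, cascade = cascade),
               function(m, x) predict(m, x), X, cl)
  expect_equal(res$accuracy, 1)
  expect_true(all(diag(res$confusion) == n))
  expect_error(ldaCascade(X[1:n, ], cl[1:n]), "two classes")
  # pure-noise features do not beat the informative prefix
  Xn <- cbind(X, matrix(rnorm(nrow(X) * 10), ncol = 10))
  colnames(Xn) <- paste0("f", 1:14)
  fitN <- ldaCascade(Xn, cl, k = 4, cascade = cascade)
  expect_true(all(fitN$features %in% 1:4))
})

test_that("equal-population discretization respects ties and monotone maps", {
  x <- c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6)
  b <- discretizeEqualPopulation(x, 5)
  expect_equal(as.numeric(table(b)), rep(2, 5))
  expect_equal(b[order(x)], rep(1:5, each = 2))
  # heavy ties: identical values share a bin
  xt <- c(rep(4, 8), 1, 9)
  bt <- discretizeEqualPopulation(xt, 5)
  expect_equal(length(unique(bt[xt == 4])), 1)
  # monotone transforms leave labels unchanged
  expect_identical(discretizeEqualPopulation(exp(x), 5), b)
  expect_error(discretizeEqualPopulation(1:3, 5), "at least")
})

test_that("mutual information has the right limits and hand values", {
  set.seed(43)
  xb <- sample(1:5, 1e4, TRUE)
  yb <- sample(1:5, 1e4, TRUE)
  expect_lt(mutualInformation(xb, yb), 0.01)
  expect_lt(abs(mutualInformation(xb, xb) - log(5)), 0.02)
  # MI(x,x) dominates MI(x,y)
  expect_gt(mutualInformation(xb, xb), mutualInformation(xb, yb))
  # hand-filled 2x2 table with add-one smoothing
  x2 <- c(1, 1, 1, 2, 2, 2, 2, 2)
  y2 <- c(1, 1, 2, 2, 2, 2, 1, 2)
  n <- 8
  nxy <- table(factor(x2, 1:2), factor(y2, 1:2))
  Px <- (tabulate(x2, 2) + 1) / (n + 2)
  Py <- (tabulate(y2, 2) + 1) / (n + 2)
  Pxy <- (as.numeric(nxy) + 1) / (n + 4)
  hand <- sum(Pxy * log(Pxy / (rep(Px, 2) * rep(Py, each = 2))))
  expect_equal(mutualInformation(x2, y2, 2, 2), hand)
})

test_that("K2 recovers a chain and the classifier follows Bayes", {
  set.seed(44)
  n <- 5000
  A <- sample(1:2, n, TRUE, prob = c(0.4, 0.6))
  B <- ifelse(runif(n) < ifelse(A == 1, 0.85, 0.2), 1L, 2L)
  C <- ifelse(runif(n) < ifelse(B == 1, 0.9, 0.15), 1L, 2L)
  df <- data.frame(class = factor(A), b = B, c = C)
  net <- k2Learn(df, maxParents = 2L, r = 2L)
  # with the order (class=A, then by MI), K2 should attach B to A and C to B
  expect_true("class" %in% net@parents[["b"]])
  expect_true("b" %in% net@parents[["c"]])
  # posteriors sum to one and argmax equals the analytic Bayes rule
  post <- bncPredict(net, df)
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  # analytic posterior for A given (B, C) - C conditionally independent of A
  pA <- c(0.4, 0.6)
  pBgA <- rbind(c(0.85, 0.15), c(0.2, 0.8))
  bayes <- vapply(seq_len(n), function(i) {
    w <- pA * pBgA[, B[i]]
    which.max(w)
  }, 0L)
  agreement <- mean(attr(post, "class") == levels(factor(A))[bayes])
  expect_gt(agreement, 0.98)
  # single feature: only the class edge is available
  df1 <- data.frame(class = factor(A), b = B)
  net1 <- k2Learn(df1, maxParents = 2L, r = 2L)
  expect_true(all(net1@parents[["b"]] %in% "class"))
})

test_that("LOOCV reproduces the majority-class baseline", {
  X <- matrix(rnorm(40), 20, 2)
  cl <- rep(c("a", "b"), c(14, 6))
  res <- loocv(function(Xt, ct) names(which.max(table(ct))),
               function(m, x) m, X, cl)
  # removing one sample of the majority class cannot flip the majority
  expect_equal(res$accuracy, 14 / 20)
  expect_equal(rownames(res$confusion), c("a", "b"))
})
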