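#' Fisher scores of features for class separation
#'
#' F_i = sum_k n_k (u_ki - u_i)^2 / sum_k n_k sigma_ki^2 over the m classes:
#' the ratio of the size-weighted between-class scatter to the size-weighted
#' within-class variance, per feature. Affine rescaling of a feature leaves
#' its score unchanged.
#'
#' @param features numeric matrix (samples x features).
#' @param classes factor/character vector of class labels (>= 2 classes with
#'   >= 2 members each).
#' @return named numeric vector of scores; a feature with zero within-class
#'   variance in every class scores \code{Inf} (flagged by a warning).
#' @export
fisherScores <- function(features, classes) {
  X <- as.matrix(features)
  cl <- as.factor(classes)
  stopifnot(nlevels(cl) >= 2L, all(table(cl) >= 2L))
  u <- colMeans(X)
  num <- numeric(ncol(X)); den <- numeric(ncol(X))
  for (k in levels(cl)) {
    sel <- cl == k
    nk <- sum(sel)
    uk <- colMeans(X[sel, , drop = FALSE])
    sk <- apply(X[sel, , drop = FALSE], 2, sd)
    num <- num + nk * (uk - u)^2
    den <- den + nk * sk^2
  }
  s <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  if (any(is.infinite(s)))
    warning("feature(s) with zero within-class variance scored Inf")
  names(s) <- colnames(X)
  s
}

#' Linear-discriminant cascade for cell-type classification
#'
#' Three binary linear discriminants applied in sequence: the first class of
#' \code{cascade} versus the rest, then the second versus the remainder, and
#' finally the last two against each other. Features are ranked by Fisher
#' score and the top \code{k} are used; when \code{k} is NULL the prefix
#' length maximizing leave-one-out accuracy is selected.
#'
#' @param features numeric matrix (samples x features).
#' @param classes class labels covering all cascade classes.
#' @param k number of Fisher-ranked features (NULL = select by LOOCV).
#' @param cascade class order; defaults to the observed classes by
#'   decreasing frequency (hepatocytes first in liver data).
#' @param kGrid candidate k values scanned when \code{k} is NULL.
#' @return an object of class \code{ldaCascade} with a
#'   \code{predict(object, newdata)} method.
#' @export
ldaCascade <- function(features, classes, k = NULL, cascade = NULL,
                       kGrid = NULL) {
  X <- as.matrix(features)
  cl <- as.character(classes)
  if (length(unique(cl)) < 2L) stop("need at least two classes")
  if (is.null(cascade)) cascade <- names(sort(table(cl), decreasing = TRUE))
  if (!all(cl %in% cascade)) stop("class absent from the cascade order")
  if (!all(cascade %in% cl)) stop("class absent from the training set")
  fs <- suppressWarnings(fisherScores(X, cl))
  rank <- order(fs, decreasing = TRUE)
  if (is.null(k)) {
    if (is.null(kGrid)) kGrid <- unique(pmin(c(2L, 4L, 8L, 12L, 16L, 24L,
                                               32L, ncol(X)), ncol(X)))
    accs <- vapply(kGrid, function(kk) {
      fit <- ldaCascade(X, cl, k = kk, cascade = cascade)
      loocv(function(Xt, ct) ldaCascade(Xt, ct, k = kk, cascade = cascade),
            function(m, x) predict(m, x), X, cl)$accuracy
    }, 0)
    k <- kGrid[which.max(accs)]
  }
  sel <- rank[seq_len(min(k, ncol(X)))]
  steps <- list()
  remaining <- seq_along(cl)
  for (s in seq_len(length(cascade) - 1L)) {
    target <- cascade[s]
    y <- factor(ifelse(cl[remaining] == target, target, ".rest"))
    if (nlevels(y) < 2L) stop("degenerate cascade step")
    Xs <- X[remaining, sel, drop = FALSE]
    keepCols <- which(apply(Xs, 2, function(v) sd(v) > 1e-12))
    fit <- MASS::lda(Xs[, keepCols, drop = FALSE], grouping = y)
    steps[[s]] <- list(target = target, fit = fit, cols = sel[keepCols])
    remaining <- remaining[cl[remaining] != target]
    if (s == length(cascade) - 1L) break
  }
  structure(list(steps = steps, cascade = cascade, features = sel,
                 fisher = fs), class = "ldaCascade")
}

#' @rdname ldaCascade
#' @param object fitted cascade.
#' @param newdata matrix (or vector) of feature values.
#' @param ... unused.
#' @export
predict.ldaCascade <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, 1) else as.matrix(newdata)
  out <- character(nrow(X))
  todo <- seq_len(nrow(X))
  for (s in seq_along(object$steps)) {
    st <- object$steps[[s]]
    if (!length(todo)) break
    pr <- predict(st$fit, X[todo, st$cols, drop = FALSE])$class
    hit <- pr == st$target
    out[todo[hit]] <- st$target
    todo <- todo[!hit]
  }
  lastTwo <- tail(object$cascade, 2L)
  if (length(todo)) {
    # the final step separates the last two classes
    st <- object$steps[[length(object$steps)]]
    pr <- predict(st$fit, X[todo, st$cols, drop = FALSE])$class
    out[todo] <- as.character(pr)
    out[todo][out[todo] == ".rest"] <- lastTwo[2]
  }
  out
}

#' Equal-population discretization
#'
#' Assigns values to \code{r} bins with populations as equal as ties allow;
#' identical values always share a bin, and any monotone transform of the
#' data yields the same labels.
#'
#' @param x numeric values (length >= r).
#' @param r number of bins.
#' @return integer bin labels in 1..r.
#' @export
discretizeEqualPopulation <- function(x, r = 5L) {
  n <- length(x)
  if (n < r) stop("need at least r values")
  o <- order(x)
  cnt <- table(factor(match(x, sort(unique(x)))))
  uv <- sort(unique(x))
  cum <- cumsum(as.numeric(cnt))
  cumMid <- cum - as.numeric(cnt) / 2
  binOfUnique <- pmin(r, pmax(1L, ceiling(cumMid * r / n)))
  binOfUnique <- as.integer(cummax(binOfUnique))   # monotone in value
  binOfUnique[match(x, uv)]
}

#' Mutual information of two discretized variables
#'
#' MI(X,Y) = sum_xy P(x,y) ln( P(x,y) / (P(x) P(y)) ) with add-one smoothed
#' probabilities P(x) = (n_x + 1)/(n + r); non-negative up to smoothing
#' bias; in nats.
#'
#' @param xb,yb integer bin labels of equal length.
#' @param rx,ry number of bins per variable (defaults to the observed
#'   maximum).
#' @return mutual information in nats.
#' @export
mutualInformation <- function(xb, yb, rx = max(xb), ry = max(yb)) {
  stopifnot(length(xb) == length(yb))
  n <- length(xb)
  nx <- tabulate(xb, rx); ny <- tabulate(yb, ry)
  nxy <- table(factor(xb, seq_len(rx)), factor(yb, seq_len(ry)))
  Px <- (nx + 1) / (n + rx)
  Py <- (ny + 1) / (n + ry)
  Pxy <- (as.numeric(nxy) + 1) / (n + rx * ry)
  Pxm <- rep(Px, times = ry); Pym <- rep(Py, each = rx)
  sum(Pxy * log(Pxy / (Pxm * Pym)))
}

#' Learn a Bayesian-network classifier structure with K2
#'
#' Nodes are the class variable followed by the discretized features sorted
#' by decreasing mutual information with the class. For each node in that
#' order, parents are greedily added from its predecessors while the K2
#' (Cooper-Herskovits) score improves, up to \code{maxParents}. Conditional
#' probability tables use add-one smoothing.
#'
#' @param data data.frame of integer bin labels; column \code{class} (factor
#'   or character) plus feature columns.
#' @param maxParents parent cap per node.
#' @param r bins per feature.
#' @return a \linkS4class{BayesNet}.
#' @export
k2Learn <- function(data, maxParents = 3L, r = 5L) {
  stopifnot("class" %in% names(data))
  cls <- as.factor(data$class)
  feats <- setdiff(names(data), "class")
  cb <- as.integer(cls)
  mi <- vapply(feats, function(f)
    mutualInformation(data[[f]], cb, r, nlevels(cls)), 0)
  ordNodes <- c("class", feats[order(mi, decreasing = TRUE)])
  card <- c(class = nlevels(cls), setNames(rep(r, length(feats)), feats))
  cols <- c(list(class = cb), lapply(data[feats], as.integer))
  n <- length(cb)
  k2score <- function(node, parents) {
    ri <- card[[node]]
    if (!length(parents)) {
      cfg <- rep(1L, n)
      q <- 1L
    } else {
      pc <- vapply(parents, function(p) cols[[p]], integer(n))
      pc <- as.matrix(pc)
      mult <- cumprod(c(1, card[parents][-length(parents)]))
      cfg <- as.integer(1 + (pc - 1) %*% mult)
      q <- prod(card[parents])
    }
    sc <- 0
    xv <- cols[[node]]
    tab <- table(factor(cfg, seq_len(q)), factor(xv, seq_len(ri)))
    Nij <- rowSums(tab)
    sc <- sum(lgamma(ri) - lgamma(Nij + ri) + rowSums(lgamma(tab + 1)))
    sc
  }
  parents <- setNames(vector("list", length(ordNodes)), ordNodes)
  for (i in seq_along(ordNodes)) {
    node <- ordNodes[i]
    if (i == 1L) { parents[[node]] <- character(0); next }
    preds <- ordNodes[seq_len(i - 1L)]
    cur <- character(0)
    curScore <- k2score(node, cur)
    repeat {
      if (length(cur) >= maxParents) break
      candScores <- vapply(setdiff(preds, cur), function(p)
        k2score(node, c(cur, p)), 0)
      if (!length(candScores) || max(candScores) <= curScore) break
      best <- names(candScores)[which.max(candScores)]
      cur <- c(cur, best)
      curScore <- max(candScores)
    }
    parents[[node]] <- cur
  }
  # CPTs with add-one smoothing
  cpts <- list()
  for (node in ordNodes) {
    ri <- card[[node]]
    ps <- parents[[node]]
    if (!length(ps)) {
      cnt <- tabulate(cols[[node]], ri)
      cpts[[node]] <- (cnt + 1) / (n + ri)
    } else {
      q <- prod(card[ps])
      pc <- as.matrix(vapply(ps, function(p) cols[[p]], integer(n)))
      mult <- cumprod(c(1, card[ps][-length(ps)]))
      cfg <- as.integer(1 + (pc - 1) %*% mult)
      tab <- table(factor(cfg, seq_len(q)), factor(cols[[node]],
                                                   seq_len(ri)))
      cpts[[node]] <- (unclass(tab) + 1) /
        (rowSums(tab) + ri)
    }
  }
  new("BayesNet", nodes = ordNodes, parents = parents, cpts = cpts,
      levels = list(class = levels(cls), card = card))
}

#' Posterior class probabilities from a K2-learned network
#'
#' P(class | features) proportional to the product of all node conditional
#' probabilities; posteriors sum to 1 per sample and the class with the
#' highest posterior is the prediction.
#'
#' @param net a \linkS4class{BayesNet} from \code{\link{k2Learn}}.
#' @param newdata data.frame of integer feature bins (same columns as in
#'   training).
#' @return matrix (samples x classes) of posteriors, with the predicted
#'   class as attribute \code{"class"}.
#' @export
bncPredict <- function(net, newdata) {
  classes <- net@levels$class
  card <- net@levels$card
  nC <- length(classes)
  ns <- nrow(newdata)
  logpost <- matrix(0, ns, nC, dimnames = list(NULL, classes))
  for (ci in seq_len(nC)) {
    for (node in net@nodes) {
      ps <- net@parents[[node]]
      xv <- if (node == "class") rep(ci, ns) else as.integer(newdata[[node]])
      if (!length(ps)) {
        logpost[, ci] <- logpost[, ci] + log(net@cpts[[node]][xv])
      } else {
        pvals <- vapply(ps, function(p)
          if (p == "class") rep(ci, ns) else as.integer(newdata[[p]]),
          integer(ns))
        pvals <- matrix(pvals, nrow = ns)
        mult <- cumprod(c(1, card[ps][-length(ps)]))
        cfg <- as.integer(1 + (pvals - 1) %*% mult)
        logpost[, ci] <- logpost[, ci] +
          log(net@cpts[[node]][cbind(cfg, xv)])
      }
    }
  }
  post <- exp(logpost - apply(logpost, 1, max))
  post <- post / rowSums(post)
  attr(post, "class") <- classes[max.col(post, ties.method = "first")]
  post
}

#' Leave-one-out cross-validation
#'
#' Each sample is predicted by a model trained on the remaining n-1; returns
#' the accuracy and the confusion matrix (rows = actual, columns =
#' predicted).
#'
#' @param trainFun function(features, classes) returning a model.
#' @param predictFun function(model, featureRow) returning a class label.
#' @param features samples x features matrix.
#' @param classes labels.
#' @return list with \code{accuracy} and \code{confusion}.
#' @export
loocv <- function(trainFun, predictFun, features, classes) {
  X <- as.matrix(features)
  cl <- as.character(classes)
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    m <- trainFun(X[-i, , drop = FALSE], cl[-i])
    pred[i] <- as.character(predictFun(m, X[i, , drop = FALSE]))
  }
  lev <- sort(unique(cl))
  conf <- table(factor(cl, lev), factor(pred, lev))
  list(accuracy = mean(pred == cl), confusion = conf, predictions = pred)
}
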