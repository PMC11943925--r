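#' Column-wise centering and scaling for multivariate modelling
#'
#' Centers every column and optionally scales: `"uv"` divides by the column
#' standard deviation (n-1 denominator; classical unit-variance autoscaling),
#' `"pareto"`
#' by its square root, `"none"` leaves columns centered only. Zero-variance
#' columns get scale 1 with a warning.
#'
#' @param X Numeric matrix with at least 2 rows.
#' @param mode `"uv"` (default), `"pareto"` or `"none"`.
#' @return List with `values` (the scaled matrix), `center`, `scale`, `mode`.
#' @export
scale_matrix <- function(X, mode = c("uv", "pareto", "none")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("X must have at least 2 rows", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (mode == "none") {
    scl <- rep(1, ncol(X))
  } else {
    s <- apply(X, 2, stats::sd)
    zero <- s == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance column(s); scale set to 1",
              call. = FALSE)
      s[zero] <- 1
    }
    scl <- if (mode == "uv") s else sqrt(s)
  }
  list(values = sweep(Xc, 2, scl, "/"), center = ctr, scale = scl,
       mode = mode)
}

encode_groups <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1)))
      stop("numeric y must be coded -1 (control) / +1 (study)",
           call. = FALSE)
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("control", "study")))
    stop("group labels must be 'control'/'study'", call. = FALSE)
  ifelse(y == "study", 1, -1)
}

#' Fit a two-class PLS-DA model by NIPALS
#'
#' Class membership is coded +1 (study) / -1 (control) and centered; the
#' bucket matrix is centered and scaled per `scaling`. Components are
#' extracted one at a time (single-response NIPALS, closed form per
#' component): weight `w_a` proportional to `X'y` (unit norm), score
#' `t_a = X w_a`, X-loading `p_a = X't_a / t_a't_a`, y-loading
#' `c_a = y't_a / t_a't_a`, then X and y are deflated. The sign of each
#' weight vector is fixed so its largest-magnitude element is positive,
#' making fits reproducible. R2Y(cum) is the fraction of class-label
#' variance explained by the first A components.
#'
#' @param X Numeric matrix (samples x buckets) or a `bucket_table`.
#' @param y Group labels (`"control"`/`"study"`) or +/-1 coding; taken from
#'   the table when `X` is a `bucket_table`.
#' @param ncomp Number of components A (default 2, matching two-dimensional
#'   score plots).
#' @param scaling Passed to [scale_matrix()].
#' @return Object of class `plsda_model` with elements `weights`, `loadings`,
#'   `scores`, `y_loadings`, `x_center`, `x_scale`, `y_center`, `scaling`,
#'   `ncomp`, `r2y_per_component`, `r2y_cum`, `vip`, `groups`, `bucket_ids`,
#'   and `q2_cum` (NA until cross-validated).
#' @export
fit_plsda <- function(X, y = NULL, ncomp = 2,
                      scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  if (inherits(X, "bucket_table")) {
    if (is.null(y)) y <- X$group
    bucket_ids <- X$bucket_ids
    X <- X$values
  } else {
    X <- as.matrix(X)
    bucket_ids <- colnames(X)
    if (is.null(bucket_ids)) bucket_ids <- sprintf("bucket%d", seq_len(ncol(X)))
  }
  if (is.null(y)) stop("y is required", call. = FALSE)
  yenc <- encode_groups(y)
  if (length(yenc) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  if (length(unique(yenc)) < 2)
    stop("both classes must be present", call. = FALSE)
  sc <- scale_matrix(X, scaling)
  Xs <- sc$values
  y_center <- mean(yenc)
  yc <- yenc - y_center
  rk <- qr(Xs)$rank
  if (ncomp < 1 || ncomp > rk)
    stop("ncomp must be between 1 and rank(X) = ", rk, call. = FALSE)

  n <- nrow(Xs); K <- ncol(Xs)
  W <- matrix(0, K, ncomp); P <- matrix(0, K, ncomp)
  Tm <- matrix(0, n, ncomp); cvec <- numeric(ncomp)
  ss0 <- sum(yc^2)
  r2cum <- numeric(ncomp)
  Xd <- Xs; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(Xd, t)) / tt
    cc <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - cc * t
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; cvec[a] <- cc
    r2cum[a] <- 1 - sum(yd^2) / ss0
  }
  model <- structure(
    list(weights = W, loadings = P, scores = Tm, y_loadings = cvec,
         x_center = sc$center, x_scale = sc$scale, y_center = y_center,
         scaling = scaling, ncomp = ncomp,
         r2y_per_component = c(r2cum[1], diff(r2cum)),
         r2y_cum = r2cum[ncomp], q2_cum = NA_real_,
         groups = ifelse(yenc > 0, "study", "control"),
         bucket_ids = bucket_ids),
    class = "plsda_model")
  model$vip <- vip_scores(model)
  model
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components, %d samples x %d buckets (%s scaling)\n",
              x$ncomp, nrow(x$scores), length(x$bucket_ids), x$scaling))
  cat(sprintf("  R2Y(cum) = %.3f%s\n", x$r2y_cum,
              if (is.na(x$q2_cum)) "" else sprintf(", Q2(cum) = %.3f", x$q2_cum)))
  invisible(x)
}

#' Predict the class response for new samples
#'
#' Applies the training centering/scaling and the PLS regression vector
#' `B = W (P'W)^-1 c` to return the continuous class response (near +1 for
#' study-like, -1 for control-like samples).
#'
#' @param object A `plsda_model`.
#' @param newdata Matrix (samples x buckets) or `bucket_table` with the same
#'   buckets as the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  if (inherits(newdata, "bucket_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$bucket_ids))
    stop("newdata has the wrong number of buckets", call. = FALSE)
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  B <- object$weights %*%
    solve(crossprod(object$loadings, object$weights), object$y_loadings)
  drop(Xs %*% B) + object$y_center
}

#' Cross-validated cumulative Q2 by withholding 1/7 of the samples
#'
#' Deterministic venetian-blind (interleaved) fold assignment within each
#' class keeps folds class-balanced without randomness: the i-th sample of a
#' class goes to fold `1 + (i-1) mod n_folds`. For each fold the model —
#' including centering and scaling — is refit on the remaining samples and
#' the held-out class responses are predicted; Q2(cum) = 1 - PRESS/SS where
#' SS is the total centered class-label sum of squares.
#'
#' @inheritParams fit_plsda
#' @param n_folds Number of cross-validation segments (default 7, i.e.
#'   withholding 1/7 of the data per round).
#' @return Cumulative Q2 (a scalar; at most 1, can be negative).
#' @export
cross_validate_q2 <- function(X, y = NULL, ncomp = 2,
                              scaling = c("uv", "pareto", "none"),
                              n_folds = 7) {
  scaling <- match.arg(scaling)
  if (inherits(X, "bucket_table")) {
    if (is.null(y)) y <- X$group
    X <- X$values
  }
  X <- as.matrix(X)
  yenc <- encode_groups(y)
  n <- nrow(X)
  if (n < n_folds) stop("need at least n_folds samples", call. = FALSE)
  fold <- integer(n)
  for (cls in unique(yenc)) {
    idx <- which(yenc == cls)
    if (length(idx) < n_folds)
      stop("class with ", length(idx),
           " samples cannot be interleaved over ", n_folds,
           " folds; reduce n_folds", call. = FALSE)
    fold[idx] <- 1 + (seq_along(idx) - 1) %% n_folds
  }
  press <- 0
  for (f in seq_len(n_folds)) {
    test <- fold == f
    if (!any(test)) next
    m <- fit_plsda(X[!test, , drop = FALSE], yenc[!test], ncomp = ncomp,
                   scaling = scaling)
    yhat <- predict(m, X[test, , drop = FALSE])
    press <- press + sum((yenc[test] - yhat)^2)
  }
  1 - press / sum((yenc - mean(yenc))^2)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_k = sqrt( K * sum_a SS_a w_ak^2 / sum_a SS_a )` with unit-norm weight
#' vectors and `SS_a = c_a^2 t_a't_a`, the class-label variance captured by
#' component a. By construction the mean squared VIP over buckets is 1, so
#' buckets with VIP > 1 are more influential than average.
#'
#' @param model A fitted `plsda_model`.
#' @return Named numeric vector of K VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  K <- nrow(model$weights)
  ssa <- model$y_loadings^2 * colSums(model$scores^2)
  W2 <- sweep(model$weights^2, 2, colSums(model$weights^2), "/")
  vip <- sqrt(K * drop(W2 %*% ssa) / sum(ssa))
  names(vip) <- model$bucket_ids
  vip
}
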