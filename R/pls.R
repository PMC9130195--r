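#' NIPALS partial least squares
#'
#' Fits a PLS model by the NIPALS algorithm: latent components are extracted
#' by alternating weight/score updates with deflation of both blocks. With a
#' single response column the inner iteration closes in one step (PLS1);
#' with a one-hot multi-response (PLS-DA) the inner loop iterates to a
#' weight-change tolerance of 1e-10 (at most 500 iterations). Each weight
#' vector is sign-fixed so its largest-magnitude element is positive, making
#' output reproducible across platforms.
#'
#' Centering (and optional unit-variance scaling) of X and centering of Y
#' are estimated from the training data and stored on the model, so
#' cross-validation folds re-estimate them automatically when they refit.
#'
#' @param x Numeric matrix (samples x variables) or a [feature_matrix()].
#' @param y Numeric response vector, or a response matrix (one column per
#'   class for discriminant analysis).
#' @param ncomp Number of latent components, at most `min(n - 1, p)`.
#' @param center,scale Center / unit-variance-scale the X columns. Leave
#'   `scale = FALSE` when x is already autoscaled.
#' @return A `pls_model`: weights `W` (p x A), loadings `P` (p x A), scores
#'   `T` (n x A), Y-loadings `Q` (m x A), coefficients `B` (p x m) on the
#'   scaled metric, centers/scales, per-component explained X-variance and
#'   Y sum of squares (`ssy`, total and per response column), and fitted
#'   values.
#' @examples
#' x <- scale(matrix(rnorm(60), 12, 5))
#' y <- x %*% c(1, -1, 0, 0, 0) + rnorm(12, sd = 0.1)
#' fit <- pls_nipals(x, y, ncomp = 2)
#' glance(fit)
#' @export
pls_nipals <- function(x, y, ncomp, center = TRUE, scale = FALSE) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  y_in <- y
  y <- as.matrix(y)
  n <- nrow(x); p <- ncol(x); m <- ncol(y)
  if (nrow(y) != n) stop("x and y are not row-aligned", call. = FALSE)
  if (ncomp > min(n - 1L, p)) {
    stop("ncomp must be <= min(n - 1, p) = ", min(n - 1L, p), call. = FALSE)
  }
  x_center <- if (center) colMeans(x) else rep(0, p)
  x_scale <- if (scale) apply(x, 2, stats::sd) else rep(1, p)
  if (any(x_scale == 0)) stop("zero-variance X column", call. = FALSE)
  y_center <- colMeans(y)
  if (all(apply(y, 2, stats::sd) == 0)) {
    stop("zero-variance response", call. = FALSE)
  }
  E <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  F_ <- sweep(y, 2, y_center)
  ssx_total <- sum(E^2)

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); Q <- matrix(0, m, ncomp)
  ssy_comp <- matrix(0, ncomp, m)
  ssx_comp <- numeric(ncomp)

  for (a in seq_len(ncomp)) {
    if (m == 1L) {
      w <- crossprod(E, F_)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) {
        stop("X residual orthogonal to response at component ", a,
             call. = FALSE)
      }
      w <- w / nw
      t_ <- E %*% w
    } else {
      u <- F_[, which.max(colSums(F_^2))]
      w_old <- rep(0, p)
      for (it in seq_len(500L)) {
        w <- crossprod(E, u)[, 1]
        w <- w / sqrt(sum(w^2))
        t_ <- E %*% w
        q_in <- crossprod(F_, t_)[, 1] / sum(t_^2)
        u <- (F_ %*% q_in) / sum(q_in^2)
        if (sqrt(sum((w - w_old)^2)) < 1e-10) break
        w_old <- w
      }
    }
    # sign convention: largest-|w| element positive
    if (w[which.max(abs(w))] < 0) {
      w <- -w; t_ <- -t_
    }
    tt <- sum(t_^2)
    p_ <- crossprod(E, t_)[, 1] / tt
    q_ <- crossprod(F_, t_)[, 1] / tt
    E <- E - tcrossprod(t_, p_)
    F_ <- F_ - tcrossprod(t_, q_)
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; Q[, a] <- q_
    ssy_comp[a, ] <- tt * q_^2
    ssx_comp[a] <- tt * sum(p_^2)
  }

  # coefficients on the centered/scaled metric: B = W (P'W)^-1 Q'
  PW <- crossprod(P, W)
  B <- W %*% solve(PW, t(Q))
  Xs <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  fitted <- sweep(Xs %*% B, 2, y_center, "+")

  structure(list(
    ncomp = ncomp, W = W, P = P, T = Tm, Q = Q, B = B,
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    ssy = ssy_comp, ssx_pct = 100 * ssx_comp / ssx_total,
    fitted = fitted, y = y, n = n, p = p, m = m,
    multi_response = m > 1L,
    response_names = colnames(y)
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", if (x$multi_response) "PLS-DA" else "PLSr", ", ",
      x$ncomp, " components, n = ", x$n, ", p = ", x$p, "\n", sep = "")
  cat("  explained X-variance (%): ",
      paste(sprintf("%.1f", x$ssx_pct), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' Applies the stored centering/scaling to new rows and returns
#' `X_scaled B + y_center`.
#'
#' @param object A [pls_nipals()] model.
#' @param newdata Matrix (or [feature_matrix()]) with the same columns as
#'   the training data.
#' @param ... Unused.
#' @return Numeric matrix of predicted responses (n_new x m); a vector-like
#'   single column for PLSr.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  newdata <- rbind(as.matrix(newdata))
  if (ncol(newdata) != object$p) {
    stop("newdata has ", ncol(newdata), " columns; model expects ", object$p,
         call. = FALSE)
  }
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  sweep(Xs %*% object$B, 2, object$y_center, "+")
}

#' Variable importance in projection (VIP)
#'
#' For variable j,
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}}
#' where `SSY_a` is the response sum of squares captured by component `a`
#' and the weight vectors are unit-norm; consequently the squared VIPs sum
#' to the number of variables. For a multi-response (PLS-DA) model,
#' per-class VIPs restrict `SSY_a` to that response column.
#'
#' @param model A fitted [pls_nipals()] model.
#' @param per_class Also return per-class VIP columns for multi-response
#'   models (default `TRUE`).
#' @return A tibble with `variable` (column index), `vip`, and for
#'   multi-response models one `vip_<class>` column per response.
#' @export
vip_scores <- function(model, per_class = TRUE) {
  stopifnot(inherits(model, "pls_model"))
  w2 <- model$W^2                       # columns already unit norm
  ssy_tot <- rowSums(model$ssy)
  if (sum(ssy_tot) <= 0) stop("model captured no response variance",
                              call. = FALSE)
  vip_from <- function(ssy_a) {
    if (sum(ssy_a) <= 0) return(rep(NA_real_, model$p))
    sqrt(model$p * as.vector(w2 %*% ssy_a) / sum(ssy_a))
  }
  out <- tibble::tibble(variable = seq_len(model$p), vip = vip_from(ssy_tot))
  if (model$multi_response && per_class) {
    cls <- model$response_names
    if (is.null(cls)) cls <- paste0("class", seq_len(model$m))
    for (k in seq_len(model$m)) {
      out[[paste0("vip_", cls[k])]] <- vip_from(model$ssy[, k])
    }
  }
  out
}

#' One-hot class encoding for PLS-DA, with class merging
#'
#' Maps each study sample's incubation day to a class column; days listed
#' together in `merges` share one column (e.g. merging days 8 and 12 yields
#' the 4-class design 1 / 4 / 8-12 / 16). Rows of the indicator matrix sum
#' to one.
#'
#' @param samples Sample metadata tibble (columns `sample_id`, `day`).
#' @param merges List of integer vectors of days to merge, e.g.
#'   `list(c(8, 12))`.
#' @param days Optional vector of admissible days; a sample whose day is
#'   not listed is an error. Default: the days observed in `samples`.
#' @return A list: `Y` (n x m indicator matrix with class-named columns),
#'   `classes` (labels in column order) and `class_of` (per-sample label).
#' @export
plsda_encode <- function(samples, merges = list(), days = NULL) {
  samples <- tibble::as_tibble(samples)
  if (any(is.na(samples$day))) {
    stop("all samples must carry a day for PLS-DA encoding", call. = FALSE)
  }
  if (!is.null(days)) {
    bad <- setdiff(samples$day, days)
    if (length(bad)) {
      stop("sample day(s) outside the class design: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  label_of <- function(d) {
    for (mg in merges) if (d %in% mg) return(paste(sort(mg), collapse = "/"))
    as.character(d)
  }
  class_of <- vapply(samples$day, label_of, character(1))
  ord <- unique(class_of[order(samples$day)])
  Y <- vapply(ord, function(cl) as.numeric(class_of == cl),
              numeric(nrow(samples)))
  Y <- matrix(Y, nrow = nrow(samples),
              dimnames = list(samples$sample_id, ord))
  list(Y = Y, classes = ord, class_of = class_of)
}

#' Assign PLS-DA class labels
#'
#' Labels each new row with the class of its maximum predicted response
#' column; exact ties go to the earliest class in encoding order and are
#' reported.
#'
#' @param model A multi-response [pls_nipals()] model.
#' @param newdata Matrix or [feature_matrix()] of new rows.
#' @param encoding The [plsda_encode()] object used to fit the model.
#' @return A tibble: `row`, `class`, `tie` (logical).
#' @export
plsda_assign <- function(model, newdata, encoding) {
  pred <- predict(model, newdata)
  idx <- apply(pred, 1, which.max)
  tie <- apply(pred, 1, function(r) sum(r == max(r)) > 1L)
  tibble::tibble(row = seq_len(nrow(pred)),
                 class = encoding$classes[idx], tie = tie)
}

#' Principal component analysis by singular value decomposition
#'
#' Centers the matrix (no additional scaling - run [autoscale()] upstream
#' when unit-variance weighting is wanted) and decomposes it. Component
#' variances are `d_k^2 / (n - 1)` and sum to the total column variance
#' (equal to p for autoscaled input). Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param x Numeric matrix or [feature_matrix()].
#' @return A list: `scores` (n x k), `loadings` (p x k), `variance` (length
#'   k), `variance_pct`, `center`.
#' @export
pca_svd <- function(x) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  s <- svd(xc)
  k <- sum(s$d > max(s$d) * 1e-12)
  flip <- vapply(seq_len(k), function(j) {
    v <- s$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(s$u[, seq_len(k), drop = FALSE] %*%
                    diag(s$d[seq_len(k)], k), 2, flip, "*")
  loadings <- sweep(s$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  variance <- s$d[seq_len(k)]^2 / (nrow(x) - 1)
  list(scores = scores, loadings = loadings, variance = variance,
       variance_pct = 100 * variance / sum(s$d^2 / (nrow(x) - 1)),
       center = ctr)
}

#' Hierarchical clustering with Ward linkage
#'
#' Agglomerative clustering of samples using Euclidean pairwise distances
#' and Ward's minimum-variance linkage (`ward.D2`, the Ward criterion on
#' untransformed Euclidean distances). Merge heights are non-decreasing.
#'
#' @param x Numeric matrix or [feature_matrix()] (rows are clustered).
#' @return An object of class `hclust`.
#' @export
hca_ward <- function(x) {
  if (inherits(x, "feature_matrix")) {
    labs <- x$samples$sample_id
    x <- x$values
    rownames(x) <- labs
  }
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}
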