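# Lean internal NIPALS core used by cross-validation and permutation loops:
# operates on already centered/scaled blocks, no sign fixing, no bookkeeping.
.nipals_core <- function(E, F_, ncomp) {
  p <- ncol(E); m <- ncol(F_)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, m, ncomp)
  for (a in seq_len(ncomp)) {
    if (m == 1L) {
      w <- crossprod(E, F_)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) {
        # residual X orthogonal to y: pad with a null component
        W <- W[, seq_len(a - 1L), drop = FALSE]
        P <- P[, seq_len(a - 1L), drop = FALSE]
        Q <- Q[, seq_len(a - 1L), drop = FALSE]
        return(list(W = W, P = P, Q = Q, ncomp = a - 1L))
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
    tt <- sum(t_^2)
    p_ <- crossprod(E, t_)[, 1] / tt
    q_ <- crossprod(F_, t_)[, 1] / tt
    E <- E - tcrossprod(t_, p_)
    F_ <- F_ - tcrossprod(t_, q_)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q_
  }
  list(W = W, P = P, Q = Q, ncomp = ncomp)
}

# held-out predictions at every component count 1..ncomp for one new row set
.predict_seq <- function(core, x_new_scaled, y_center, ncomp) {
  A <- min(core$ncomp, ncomp)
  PW <- crossprod(core$P, core$W)
  out <- vector("list", ncomp)
  for (a in seq_len(ncomp)) {
    aa <- min(a, A)
    if (aa == 0L) {
      out[[a]] <- matrix(rep(y_center, each = nrow(x_new_scaled)),
                         nrow(x_new_scaled))
      next
    }
    B <- core$W[, seq_len(aa), drop = FALSE] %*%
      solve(PW[seq_len(aa), seq_len(aa), drop = FALSE],
            t(core$Q[, seq_len(aa), drop = FALSE]))
    out[[a]] <- sweep(x_new_scaled %*% B, 2, y_center, "+")
  }
  out
}

.scale_cols <- function(x, center, scl) sweep(sweep(x, 2, center), 2, scl, "/")

#' Leave-one-out cross-validation of a PLS model
#'
#' For each component count up to `ncomp_max`, computes the root mean
#' squared error of calibration (RMSEC, training fit) and of leave-one-out
#' cross-validation (RMSECV). Each fold removes one sample, re-estimates
#' centering (and scaling, when requested) on the remainder, refits NIPALS
#' and predicts the held-out sample, so no information leaks from the
#' held-out row. The component count is then chosen by the parsimony rule
#' of [select_components()], and R-squared / Q-squared are reported at the
#' chosen count.
#'
#' @param x Numeric matrix or [feature_matrix()].
#' @param y Response vector or indicator matrix.
#' @param ncomp_max Largest component count to evaluate
#'   (at most `min(n - 2, p)`).
#' @param scale Re-estimate unit-variance scaling inside folds (use `TRUE`
#'   when x is on the transformed-but-unscaled metric).
#' @param parsimony_tol Tolerance of the component-selection rule.
#' @return A `cv_result`: tibble `components` (ncomp, rmsec, rmsecv),
#'   chosen `ncomp`, per-sample CV residuals and predictions at the chosen
#'   count, `r2`, `q2`.
#' @export
loo_cv <- function(x, y, ncomp_max, scale = TRUE, parsimony_tol = 0.01) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop("leave-one-out needs n >= 3", call. = FALSE)
  if (ncomp_max > min(n - 2L, p)) {
    stop("ncomp_max must be <= min(n - 2, p) = ", min(n - 2L, p),
         call. = FALSE)
  }

  full <- pls_nipals(x, y, ncomp = ncomp_max, center = TRUE, scale = scale)
  # training fitted values at every component count from the score expansion
  rmsec <- numeric(ncomp_max)
  cum <- matrix(rep(full$y_center, each = n), n)
  for (a in seq_len(ncomp_max)) {
    cum <- cum + tcrossprod(full$T[, a], full$Q[, a])
    rmsec[a] <- sqrt(mean((y - cum)^2))
  }

  cv_pred <- array(0, dim = c(n, ncol(y), ncomp_max))
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]; yt <- y[-i, , drop = FALSE]
    ctr <- colMeans(xt)
    scl <- if (scale) apply(xt, 2, stats::sd) else rep(1, p)
    if (any(scl == 0)) scl[scl == 0] <- 1
    core <- .nipals_core(.scale_cols(xt, ctr, scl),
                         sweep(yt, 2, colMeans(yt)), ncomp_max)
    preds <- .predict_seq(core, .scale_cols(x[i, , drop = FALSE], ctr, scl),
                          colMeans(yt), ncomp_max)
    for (a in seq_len(ncomp_max)) cv_pred[i, , a] <- preds[[a]]
  }
  rmsecv <- vapply(seq_len(ncomp_max), function(a) {
    sqrt(mean((y - matrix(cv_pred[, , a], n, ncol(y)))^2))
  }, numeric(1))

  comp_tbl <- tibble::tibble(ncomp = seq_len(ncomp_max),
                             rmsec = rmsec, rmsecv = rmsecv)
  chosen <- select_components(comp_tbl, parsimony_tol)
  cv_at <- matrix(cv_pred[, , chosen], n, ncol(y))
  press_res <- y - cv_at
  sstot <- sum(sweep(y, 2, colMeans(y))^2)
  if (sstot == 0) stop("zero total response variance", call. = FALSE)
  fit_at <- matrix(rep(full$y_center, each = n), n)
  for (a in seq_len(chosen)) {
    fit_at <- fit_at + tcrossprod(full$T[, a], full$Q[, a])
  }
  structure(list(
    components = comp_tbl, ncomp = chosen,
    cv_residuals = press_res,
    cv_pred = cv_at,
    fitted = fit_at, y = y,
    r2 = 1 - sum((y - fit_at)^2) / sstot,
    q2 = 1 - sum(press_res^2) / sstot,
    scale = scale
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> chosen ncomp = ", x$ncomp,
      sprintf(", R2 = %.4f, Q2 = %.4f\n", x$r2, x$q2), sep = "")
  print(x$components)
  invisible(x)
}

#' Choose the number of latent components
#'
#' Takes the smallest component count whose RMSECV is within
#' `parsimony_tol` (fractionally) of the minimum RMSECV - a one-standard-rule
#' flavoured parsimony criterion that avoids buying complexity for noise.
#'
#' @param cv Either a `cv_result` or its `components` tibble
#'   (columns `ncomp`, `rmsecv`).
#' @param parsimony_tol Fractional tolerance (default 0.01).
#' @return The chosen component count (integer).
#' @export
select_components <- function(cv, parsimony_tol = 0.01) {
  tbl <- if (inherits(cv, "cv_result")) cv$components else cv
  lim <- (1 + parsimony_tol) * min(tbl$rmsecv)
  as.integer(min(tbl$ncomp[tbl$rmsecv <= lim]))
}

#' Training and cross-validated explained variance
#'
#' `R2 = 1 - SSres/SStot` on the training fit and
#' `Q2 = 1 - PRESS/SStot` with cross-validation residuals; Q2 may be
#' negative and is never clipped.
#'
#' @param y Observed response (vector or matrix).
#' @param fitted Training fitted values.
#' @param cv_pred Cross-validated predictions.
#' @return A one-row tibble with `r2` and `q2`.
#' @export
r2_q2 <- function(y, fitted, cv_pred) {
  y <- as.matrix(y)
  sstot <- sum(sweep(y, 2, colMeans(y))^2)
  if (sstot == 0) stop("zero total response variance", call. = FALSE)
  tibble::tibble(r2 = 1 - sum((y - as.matrix(fitted))^2) / sstot,
                 q2 = 1 - sum((y - as.matrix(cv_pred))^2) / sstot)
}

# internal: centered/scaled design blocks for the full data and every LOO
# fold; X never changes across permutations, so this is computed once
.precompute_loo <- function(x, scale) {
  n <- nrow(x); p <- ncol(x)
  scale_block <- function(xt, xnew) {
    ctr <- colMeans(xt)
    E <- sweep(xt, 2, ctr)
    if (scale) {
      scl <- sqrt(colSums(E^2) / (nrow(xt) - 1))
      scl[scl == 0] <- 1
      E <- sweep(E, 2, scl, "/")
      xnew <- sweep(sweep(xnew, 2, ctr), 2, scl, "/")
    } else {
      xnew <- sweep(xnew, 2, ctr)
    }
    list(E = E, xnew = xnew)
  }
  folds <- lapply(seq_len(n), function(i) {
    scale_block(x[-i, , drop = FALSE], x[i, , drop = FALSE])
  })
  full <- scale_block(x, x)
  list(full = full, folds = folds, n = n)
}

# internal: fast single-response Q2/residuals on precomputed design blocks
.pls1_q2 <- function(pre, y, ncomp, want_residuals = TRUE) {
  n <- pre$n
  fit_pred <- function(E, yc_centered, xnew) {
    core <- .nipals_core(E, cbind(yc_centered), ncomp)
    A <- core$ncomp
    if (A == 0L) return(rep(0, nrow(xnew)))
    PW <- crossprod(core$P, core$W)
    B <- core$W %*% solve(PW, t(core$Q))
    as.vector(xnew %*% B)
  }
  ybar <- mean(y)
  sp_pred <- ybar + fit_pred(pre$full$E, y - ybar, pre$full$xnew)
  cv_pred <- numeric(n)
  for (i in seq_len(n)) {
    yt <- y[-i]
    yc <- mean(yt)
    cv_pred[i] <- yc + fit_pred(pre$folds[[i]]$E, yt - yc,
                                pre$folds[[i]]$xnew)
  }
  sstot <- sum((y - ybar)^2)
  list(
    q2 = 1 - sum((y - cv_pred)^2) / sstot,
    r2 = 1 - sum((y - sp_pred)^2) / sstot,
    sp_abs = if (want_residuals) abs(y - sp_pred) else NULL,
    cv_abs = if (want_residuals) abs(y - cv_pred) else NULL
  )
}

# internal: Q2 and per-sample absolute residuals (self-prediction and CV)
# for one response, lean path used by the permutation loop
.fit_q2 <- function(x, y, ncomp, scale, want_residuals = TRUE) {
  n <- nrow(x)
  y <- as.matrix(y)
  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scl[scl == 0] <- 1
  yc <- colMeans(y)
  core <- .nipals_core(.scale_cols(x, ctr, scl), sweep(y, 2, yc), ncomp)
  sp_pred <- .predict_seq(core, .scale_cols(x, ctr, scl), yc,
                          ncomp)[[ncomp]]
  cv_pred <- matrix(0, n, ncol(y))
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]; yt <- y[-i, , drop = FALSE]
    ci <- colMeans(xt)
    si <- if (scale) apply(xt, 2, stats::sd) else rep(1, ncol(x))
    si[si == 0] <- 1
    corei <- .nipals_core(.scale_cols(xt, ci, si),
                          sweep(yt, 2, colMeans(yt)), ncomp)
    cv_pred[i, ] <- .predict_seq(corei,
                                 .scale_cols(x[i, , drop = FALSE], ci, si),
                                 colMeans(yt), ncomp)[[ncomp]]
  }
  sstot <- sum(sweep(y, 2, yc)^2)
  list(
    q2 = 1 - sum((y - cv_pred)^2) / sstot,
    r2 = 1 - sum((y - sp_pred)^2) / sstot,
    sp_abs = if (want_residuals) sqrt(rowSums((y - sp_pred)^2)) else NULL,
    cv_abs = if (want_residuals) sqrt(rowSums((y - cv_pred)^2)) else NULL
  )
}

#' Permutation test of a PLS model
#'
#' Refits the model on row-shuffled responses to build a null distribution
#' of cross-validated performance. The empirical p-value is the rank of the
#' true model's Q2 in the null,
#' `p = (1 + #\{Q2_perm >= Q2_true\}) / (1 + n_perm)`, never zero. In
#' addition, three paired tests (Wilcoxon signed-rank, sign test, paired
#' t-test) compare the true model's per-sample absolute residuals against
#' each permuted model's - separately for self-prediction (SP) and
#' cross-validated (CV) residuals - with the per-permutation p-values
#' aggregated by their median and each test reported as the larger
#' (more conservative) of its SP and CV values.
#'
#' @param x Numeric matrix or [feature_matrix()].
#' @param y Response vector or indicator matrix.
#' @param ncomp Component count of the model under test.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation draws (mandatory).
#' @param scale Re-estimate scaling inside fits (see [loo_cv()]).
#' @param paired_tests Compute the three paired residual tests (disable for
#'   large calibration studies that only need the empirical p).
#' @return A `permutation_result`: `q2_true`, `empirical_p`, tibble
#'   `permutations` (q2, y_correlation per draw), and when requested the
#'   per-test p-values `p_wilcoxon`, `p_sign`, `p_ttest` (each
#'   `max(SP, CV)` of the median aggregates).
#' @export
permutation_test <- function(x, y, ncomp, n_perm = 1000L, seed,
                             scale = TRUE, paired_tests = TRUE) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  n <- nrow(x)

  pls1 <- ncol(y) == 1L
  pre <- if (pls1) .precompute_loo(x, scale) else NULL
  true_fit <- if (pls1) .pls1_q2(pre, as.vector(y), ncomp)
              else .fit_q2(x, y, ncomp, scale)
  set.seed(seed)
  q2_perm <- numeric(n_perm)
  ycor <- numeric(n_perm)
  pw_sp <- pw_cv <- ps_sp <- ps_cv <- pt_sp <- pt_cv <-
    if (paired_tests) numeric(n_perm) else NULL
  yv <- as.vector(y)

  paired_p <- function(true_abs, perm_abs) {
    d <- true_abs - perm_abs
    pw <- tryCatch(
      suppressWarnings(stats::wilcox.test(true_abs, perm_abs, paired = TRUE,
                                          alternative = "less")$p.value),
      error = function(e) 1)
    nz <- sum(d != 0)
    ps <- if (nz == 0) 1 else
      stats::binom.test(sum(d < 0), nz, alternative = "greater")$p.value
    pt <- if (stats::sd(d) == 0) 1 else
      stats::t.test(d, alternative = "less")$p.value
    c(pw, ps, pt)
  }

  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    yp <- y[idx, , drop = FALSE]
    fitp <- if (pls1) {
      .pls1_q2(pre, as.vector(yp), ncomp, want_residuals = paired_tests)
    } else {
      .fit_q2(x, yp, ncomp, scale, want_residuals = paired_tests)
    }
    q2_perm[k] <- fitp$q2
    ycor[k] <- suppressWarnings(stats::cor(yv, as.vector(yp)))
    if (paired_tests) {
      # residuals of the permuted model measured against its own (permuted)
      # response, paired with the true model's residuals by sample position
      sp <- paired_p(true_fit$sp_abs, fitp$sp_abs)
      cv <- paired_p(true_fit$cv_abs, fitp$cv_abs)
      pw_sp[k] <- sp[1]; ps_sp[k] <- sp[2]; pt_sp[k] <- sp[3]
      pw_cv[k] <- cv[1]; ps_cv[k] <- cv[2]; pt_cv[k] <- cv[3]
    }
  }

  out <- list(
    q2_true = true_fit$q2, r2_true = true_fit$r2,
    n_perm = n_perm, seed = seed, ncomp = ncomp,
    empirical_p = (1 + sum(q2_perm >= true_fit$q2)) / (1 + n_perm),
    permutations = tibble::tibble(q2 = q2_perm, y_correlation = ycor)
  )
  if (paired_tests) {
    out$p_wilcoxon <- max(stats::median(pw_sp), stats::median(pw_cv))
    out$p_sign <- max(stats::median(ps_sp), stats::median(ps_cv))
    out$p_ttest <- max(stats::median(pt_sp), stats::median(pt_cv))
  }
  structure(out, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> Q2 = %.4f, empirical p = %.4g (%d permutations)\n",
              x$q2_true, x$empirical_p, x$n_perm))
  if (!is.null(x$p_wilcoxon)) {
    cat(sprintf("  paired tests (max of SP, CV): Wilcoxon %.4g, sign %.4g, t %.4g\n",
                x$p_wilcoxon, x$p_sign, x$p_ttest))
  }
  invisible(x)
}

#' ROC curve, AUC and Youden-optimal threshold
#'
#' Builds the receiver operating characteristic for one class score by
#' trapezoidal integration over all distinct thresholds and reports the
#' threshold maximizing Youden's J (sensitivity + specificity - 1).
#'
#' @param scores Numeric predicted scores (higher = more positive).
#' @param truth Logical (or two-level) vector of true class membership.
#' @return A `roc_result`: `auc`, `curve` (tibble fpr/tpr/threshold),
#'   `youden` (one-row tibble with threshold, sensitivity, specificity).
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L) {
    stop("truth must contain both classes", call. = FALSE)
  }
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 quiet = TRUE, direction = "<")
  best <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  curve <- tibble::tibble(
    threshold = r$thresholds,
    fpr = 1 - r$specificities,
    tpr = r$sensitivities
  )
  curve <- curve[order(curve$fpr, curve$tpr), ]
  structure(list(
    auc = as.numeric(pROC::auc(r)),
    curve = curve,
    youden = tibble::tibble(threshold = best$threshold[1],
                            sensitivity = best$sensitivity[1],
                            specificity = best$specificity[1])
  ), class = "roc_result")
}

#' Per-class ROC and confusion matrix for a PLS-DA model
#'
#' One-vs-rest ROC for every class column of a fitted discriminant model,
#' plus the confusion matrix under the maximum-response assignment rule.
#'
#' @param model A multi-response [pls_nipals()] model.
#' @param x Training data (matrix or [feature_matrix()]).
#' @param encoding The [plsda_encode()] object used for the fit.
#' @return A list: `per_class` (tibble class/auc/threshold/sensitivity/
#'   specificity), `rocs` (list of `roc_result`), `confusion` (table),
#'   `accuracy`.
#' @export
plsda_roc <- function(model, x, encoding) {
  pred <- predict(model, x)
  per <- list()
  rocs <- list()
  for (k in seq_along(encoding$classes)) {
    cl <- encoding$classes[k]
    rr <- roc_auc(pred[, k], encoding$class_of == cl)
    rocs[[cl]] <- rr
    per[[k]] <- tibble::tibble(class = cl, auc = rr$auc,
                               threshold = rr$youden$threshold,
                               sensitivity = rr$youden$sensitivity,
                               specificity = rr$youden$specificity)
  }
  assigned <- plsda_assign(model, x, encoding)
  confusion <- table(truth = encoding$class_of, assigned = assigned$class)
  list(per_class = dplyr::bind_rows(per), rocs = rocs, confusion = confusion,
       accuracy = mean(assigned$class == encoding$class_of))
}
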