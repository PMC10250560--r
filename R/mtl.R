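#' Fit an l1-regularised multi-task least-squares model
#'
#' Jointly fits linear models for several related outcomes (tasks) by
#' minimising
#' \deqn{\sum_{i=1}^{t} \|X_i W_i - Y_i\|_F^2 + \rho_1 \|W\|_1
#'   + \rho_{L2} \|W\|_F^2}
#' over the p x t weight matrix W. The l1 penalty induces feature
#' sparsity across tasks; the optional ridge term stabilises the fit. The
#' motivating use is joint prediction of a cognitive score (MMSE) and a
#' mobility score (TUG) from the six DTUEMP metrics, where both outcomes
#' are expected to depend on the same small subset of movement features:
#' sharing the regularisation level (selected once for all tasks, see
#' [cv_mtl_lasso()]) lets the related tasks stabilise each other's model
#' selection, which is the practical benefit of multi-task learning at
#' small cohort sizes.
#'
#' The objective is minimised by monotone accelerated proximal gradient
#' descent (FISTA with a monotonicity safeguard): the ridge term is
#' folded into the smooth part and the l1 term handled by its
#' soft-thresholding proximal operator. Outcomes are centred per task, so
#' intercepts are the task means; predictors are z-scored by default and
#' the scale is stored for prediction. Iteration stops when the
#' subgradient optimality residual (the KKT residual, which is zero
#' exactly at a minimiser) drops below `tol`, or after `max_iter`
#' iterations (non-convergence sets a flag and warns; it is never
#' silent).
#'
#' @param X predictor matrix (n x p), shared by all tasks, or a list of t
#'   per-task matrices with a common number of columns.
#' @param Y outcome matrix (n x t, one column per task), or a list of t
#'   numeric vectors matching the rows of `X`.
#' @param rho1 non-negative l1 penalty weight.
#' @param rhoL2 non-negative ridge penalty weight.
#' @param standardize z-score the predictor columns before fitting
#'   (default TRUE; the scale is computed from the training rows and
#'   stored in the fit).
#' @param tol subgradient (KKT) residual convergence tolerance.
#' @param max_iter iteration cap.
#' @return An object of class `"mtl_lasso"`: list with `W` (p x t weights
#'   on the standardized predictor scale), `intercepts`, `rho1`, `rhoL2`,
#'   `center`/`scale` (standardization state), `objective` (the
#'   non-increasing trace), `converged`, `iterations`, `tasks`,
#'   `features`.
#' @seealso [stl_lasso()] for the single-task benchmark,
#'   [cv_mtl_lasso()] for cross-validated MAPE, [rho1_max()] for the
#'   critical penalty.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 42))
#' fit <- mtl_lasso(dtuemp_predictors(co), cbind(mmse = co$mmse, tug = co$tug),
#'                  rho1 = 5)
#' coef(fit)
mtl_lasso <- function(X, Y, rho1 = 0, rhoL2 = 0, standardize = TRUE,
                      tol = 1e-6, max_iter = 10000L) {
  check_number(rho1, "rho1", lower = 0)
  check_number(rhoL2, "rhoL2", lower = 0)
  prob <- as_mtl_problem(X, Y)
  t_tasks <- length(prob$X)
  p <- ncol(prob$X[[1]])

  # Predictors are always centred so that per-task outcome centring makes
  # the intercepts exactly the task means; `standardize` controls the
  # scaling to unit SD. With a design shared by all tasks the scale is
  # that matrix's own column mean/SD; distinct per-task designs pool rows.
  allX <- pooled_design(prob$X)
  ctr <- colMeans(allX)
  if (standardize) {
    scl <- apply(allX, 2L, stats::sd)
    zero <- which(scl == 0)
    if (length(zero)) {
      stop_dtuemp("zero-variance feature: %s",
                  paste(prob$features[zero], collapse = ", "))
    }
  } else {
    scl <- rep(1, p)
  }
  Xs <- lapply(prob$X, function(x) sweep(sweep(x, 2L, ctr), 2L, scl, "/"))

  intercepts <- vapply(prob$Y, mean, numeric(1))
  Yc <- Map(function(y, m) y - m, prob$Y, intercepts)

  sol <- solve_mtl_apg(Xs, Yc, rho1, rhoL2, tol, max_iter)
  if (!sol$converged) {
    warning(sprintf(
      "mtl_lasso did not converge in %d iterations (KKT residual %.3g)",
      max_iter, sol$kkt), call. = FALSE)
  }

  dimnames(sol$W) <- list(prob$features, prob$tasks)
  names(intercepts) <- prob$tasks
  structure(list(
    W = sol$W, intercepts = intercepts, rho1 = rho1, rhoL2 = rhoL2,
    center = stats::setNames(ctr, prob$features),
    scale = stats::setNames(scl, prob$features),
    standardize = standardize,
    objective = sol$trace, converged = sol$converged,
    iterations = sol$iterations,
    tasks = prob$tasks, features = prob$features,
    call = match.call()
  ), class = "mtl_lasso")
}

# Design used for the standardization scale: the single matrix when all
# tasks share it, otherwise the row-bound per-task designs.
pooled_design <- function(Xl) {
  shared <- all(vapply(Xl, identical, logical(1), Xl[[1]]))
  if (shared) Xl[[1]] else do.call(rbind, Xl)
}

# Normalise (X, Y) input into per-task lists with names.
as_mtl_problem <- function(X, Y) {
  if (!is.list(X)) {
    X <- as.matrix(X)
    if (is.list(Y)) {
      Xl <- rep(list(X), length(Y))
      Yl <- Y
    } else {
      Y <- as.matrix(Y)
      Xl <- rep(list(X), ncol(Y))
      Yl <- lapply(seq_len(ncol(Y)), function(j) Y[, j])
      names(Yl) <- colnames(Y)
    }
  } else {
    Xl <- lapply(X, as.matrix)
    Yl <- if (is.list(Y)) Y else lapply(seq_len(ncol(as.matrix(Y))),
                                        function(j) as.matrix(Y)[, j])
  }
  if (length(Xl) != length(Yl)) {
    stop_dtuemp("number of tasks in X (%d) and Y (%d) differ",
                length(Xl), length(Yl))
  }
  p <- unique(vapply(Xl, ncol, integer(1)))
  if (length(p) != 1L) stop_dtuemp("all tasks must share the feature dimension")
  for (i in seq_along(Xl)) {
    if (nrow(Xl[[i]]) != length(Yl[[i]])) {
      stop_dtuemp("task %d: %d rows in X but %d outcomes",
                  i, nrow(Xl[[i]]), length(Yl[[i]]))
    }
    if (any(!is.finite(Xl[[i]])) || any(!is.finite(Yl[[i]]))) {
      stop_dtuemp("task %d: non-finite values in X or Y", i)
    }
  }
  tasks <- names(Yl)
  if (is.null(tasks) || any(tasks == "")) {
    tasks <- paste0("task_", seq_along(Yl))
  }
  features <- colnames(Xl[[1]])
  if (is.null(features)) features <- paste0("x", seq_len(p))
  list(X = Xl, Y = Yl, tasks = tasks, features = features)
}

# Monotone FISTA on the centred, standardized problem.
solve_mtl_apg <- function(Xs, Yc, rho1, rhoL2, tol, max_iter) {
  t_tasks <- length(Xs)
  p <- ncol(Xs[[1]])
  XtX <- lapply(Xs, crossprod)
  Xty <- Map(function(x, y) crossprod(x, y), Xs, Yc)
  yty <- vapply(Yc, function(y) sum(y^2), numeric(1))

  # Lipschitz constant of the smooth part's gradient
  lip <- 2 * max(vapply(XtX, function(m) max(eigen(m, symmetric = TRUE,
                                                   only.values = TRUE)$values),
                        numeric(1))) + 2 * rhoL2
  if (lip <= 0) lip <- 1

  obj <- function(W) {
    f <- rhoL2 * sum(W^2)
    for (i in seq_len(t_tasks)) {
      w <- W[, i]
      f <- f + drop(crossprod(w, XtX[[i]] %*% w)) -
        2 * drop(crossprod(w, Xty[[i]])) + yty[i]
    }
    f + rho1 * sum(abs(W))
  }
  grad <- function(W) {
    G <- matrix(0, p, t_tasks)
    for (i in seq_len(t_tasks)) {
      G[, i] <- 2 * (XtX[[i]] %*% W[, i] - Xty[[i]])
    }
    G + 2 * rhoL2 * W
  }
  soft <- function(W, thr) sign(W) * pmax(abs(W) - thr, 0)
  # subgradient optimality residual: zero exactly at a minimiser
  kkt_residual <- function(W) {
    G <- grad(W)
    active <- W != 0
    r <- pmax(abs(G) - rho1, 0)          # inactive entries
    r[active] <- abs(G[active] + rho1 * sign(W[active]))
    max(r)
  }

  Wx <- matrix(0, p, t_tasks)   # monotone iterate
  Wy <- Wx                      # extrapolated point
  tk <- 1
  fx <- obj(Wx)
  trace <- fx
  converged <- FALSE
  last_change <- Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Wz <- soft(Wy - grad(Wy) / lip, rho1 / lip)
    fz <- obj(Wz)
    if (fz <= fx) {           # accept the accelerated step
      tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
      Wy <- Wz + ((tk - 1) / tk1) * (Wz - Wx)
      prev <- fx
      Wx <- Wz
      fx <- fz
      tk <- tk1
      trace <- c(trace, fx)
      last_change <- abs(prev - fx) / max(1, abs(prev))
      # optimality-based stopping: an objective-change test alone can
      # fire while the subgradient residual is still appreciable
      if (kkt_residual(Wx) < tol) {
        converged <- TRUE
        break
      }
    } else {
      # monotone safeguard: reject the step and restart the momentum at
      # the best iterate (adaptive restart). A rejected step taken from a
      # restarted (momentum-free) point is a plain proximal-gradient step
      # that failed to improve the objective: the iterate is stationary
      # to machine precision.
      if (tk == 1 || max(abs(Wz - Wx)) < 1e-9) {
        converged <- TRUE
        trace <- c(trace, fx)
        last_change <- 0
        break
      }
      tk <- 1
      Wy <- Wx
      trace <- c(trace, fx)
    }
  }
  list(W = Wx, trace = trace, converged = converged, iterations = iter,
       last_change = last_change, kkt = kkt_residual(Wx))
}

#' Critical l1 penalty above which the multi-task fit is empty
#'
#' The smallest `rho1` at which W = 0 satisfies the subgradient optimality
#' condition of the multi-task objective: the maximum over tasks and
#' features of `|2 X_i' Y_i|` after the same standardization and
#' per-task centring the fit applies. Any `rho1` at or above this value
#' yields an exactly zero weight matrix; it anchors the penalty grids of
#' [cv_mtl_lasso()].
#'
#' @inheritParams mtl_lasso
#' @return A single non-negative number.
#' @export
rho1_max <- function(X, Y, standardize = TRUE) {
  prob <- as_mtl_problem(X, Y)
  allX <- pooled_design(prob$X)
  ctr <- colMeans(allX)
  if (standardize) {
    scl <- apply(allX, 2L, stats::sd)
    if (any(scl == 0)) stop_dtuemp("zero-variance feature")
  } else {
    scl <- rep(1, ncol(allX))
  }
  m <- 0
  for (i in seq_along(prob$X)) {
    xs <- sweep(sweep(prob$X[[i]], 2L, ctr), 2L, scl, "/")
    yc <- prob$Y[[i]] - mean(prob$Y[[i]])
    m <- max(m, max(abs(2 * crossprod(xs, yc))))
  }
  m
}

#' Single-task Lasso benchmark
#'
#' The single-task counterpart of [mtl_lasso()]: the same solver run on
#' one outcome, so any performance difference against the multi-task fit
#' is attributable to sharing information across tasks, not to solver
#' details.
#'
#' @param X predictor matrix (n x p).
#' @param y outcome vector.
#' @inheritParams mtl_lasso
#' @return An `"mtl_lasso"` fit with a single task.
#' @export
stl_lasso <- function(X, y, rho1 = 0, rhoL2 = 0, standardize = TRUE,
                      tol = 1e-6, max_iter = 10000L) {
  Y <- matrix(y, ncol = 1L)
  colnames(Y) <- "task_1"
  mtl_lasso(X, Y, rho1 = rho1, rhoL2 = rhoL2, standardize = standardize,
            tol = tol, max_iter = max_iter)
}

#' @export
print.mtl_lasso <- function(x, ...) {
  nz <- colSums(x$W != 0)
  cat(sprintf(
    "l1-regularised %s least-squares fit (rho1 = %g, rhoL2 = %g)\n",
    if (ncol(x$W) > 1L) "multi-task" else "single-task", x$rho1, x$rhoL2))
  cat(sprintf("  %d features, %d task(s); nonzero weights per task: %s\n",
              nrow(x$W), ncol(x$W),
              paste(sprintf("%s=%d", x$tasks, nz), collapse = ", ")))
  cat(sprintf("  converged: %s after %d iterations (objective %.6g)\n",
              x$converged, x$iterations, tail(x$objective, 1L)))
  invisible(x)
}

#' @export
coef.mtl_lasso <- function(object, ...) {
  rbind(`(intercept)` = object$intercepts, object$W)
}

#' @rdname mtl_lasso
#' @param object,newdata fitted model and predictor matrix (or data frame
#'   containing the fit's feature columns) for the predict method.
#' @param ... unused.
#' @export
predict.mtl_lasso <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$features, names(newdata))
    if (length(miss)) stop_dtuemp("newdata lacks feature columns: %s",
                                  paste(miss, collapse = ", "))
    newdata <- as.matrix(newdata[object$features])
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$W)) {
    stop_dtuemp("newdata has %d columns; fit uses %d features",
                ncol(newdata), nrow(object$W))
  }
  Xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  pred <- Xs %*% object$W
  sweep(pred, 2L, object$intercepts, "+")
}

#' @export
summary.mtl_lasso <- function(object, ...) {
  out <- list(coef = coef(object), rho1 = object$rho1, rhoL2 = object$rhoL2,
              converged = object$converged, iterations = object$iterations,
              objective = tail(object$objective, 1L),
              nonzero = colSums(object$W != 0))
  class(out) <- "summary.mtl_lasso"
  out
}

#' @export
print.summary.mtl_lasso <- function(x, ...) {
  cat(sprintf("rho1 = %g, rhoL2 = %g; final objective %.6g (%s, %d iters)\n",
              x$rho1, x$rhoL2, x$objective,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("Coefficients (standardized predictor scale):\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
plot.mtl_lasso <- function(x, ...) {
  graphics::plot(seq_along(x$objective) - 1L, x$objective, type = "l",
                 xlab = "iteration", ylab = "objective",
                 main = "Proximal-gradient objective trace", ...)
  invisible(x)
}

#' Mean absolute percentage error
#'
#' `100 * mean(|y - yhat| / |y|)`, with the conventional accuracy label:
#' below 5% high, 5-25% moderate, above 25% unacceptable. Undefined when
#' any observed outcome is zero (MMSE and TUG are positive by scale).
#'
#' @param y observed outcomes (all nonzero).
#' @param yhat predictions.
#' @return A number with attribute `label`.
#' @export
#' @examples
#' mape(c(1, 2, 4), c(2, 2, 2))  # 50
mape <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_dtuemp("lengths differ")
  if (any(!is.finite(y)) || any(!is.finite(yhat))) {
    stop_dtuemp("inputs must be finite")
  }
  if (any(y == 0)) stop_dtuemp("MAPE undefined: observed outcome equals 0")
  m <- 100 * mean(abs(y - yhat) / abs(y))
  structure(m, label = label_mape(m))
}

#' Extract the DTUEMP predictor columns of a cohort table
#'
#' @param cohort a `"cohort_table"` or data frame with `metric_*` columns.
#' @return Numeric matrix of the metric columns.
#' @export
dtuemp_predictors <- function(cohort) {
  cols <- grep("^metric_", names(cohort), value = TRUE)
  if (!length(cols)) stop_dtuemp("no metric_* columns found")
  as.matrix(as.data.frame(cohort)[cols])
}
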