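#' Build the covariate matrix used by the learned members
#'
#' All members share the same three covariates: age in years, a male
#' indicator, and the natural log of serum creatinine (the regression
#' equation is log-linear in creatinine, so the learners see the same
#' scale).
#'
#' @param cohort a cohort data frame with columns `age`, `sex`, `scr`.
#' @return A data frame with columns `age`, `sex_male` (0/1) and `log_scr`,
#'   one row per record, order preserved.
#' @export
#' @examples
#' build_features(data.frame(age = 60, sex = "M", scr = 1))
build_features <- function(cohort) {
  cohort <- check_cohort(cohort)
  data.frame(age = as.numeric(cohort$age),
             sex_male = as.numeric(cohort$sex == "male"),
             log_scr = log(cohort$scr))
}

feature_names <- c("age", "sex_male", "log_scr")

standardize_features <- function(X, center, scale) {
  X <- as.matrix(X[, feature_names, drop = FALSE])
  sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
}

#' The regression-equation member
#'
#' Wraps the piecewise estimating equation of [estimate_gfr_regression()]
#' in the common member-model interface so that it can sit inside a
#' [gfr_ensemble()] alongside trained members.  It needs no training and
#' carries no fitted state.
#'
#' @return An object of class `c("gfr_regression", "gfr_member")`.
#' @export
#' @examples
#' predict(regression_member(), data.frame(age = 0, sex = "F", scr = 1.2))
regression_member <- function() {
  structure(list(kind = "regression"),
            class = c("gfr_regression", "gfr_member"))
}

#' Train a learned GFR member model
#'
#' Fits one of the two flexible member models on a development cohort with
#' measured GFR, using the [build_features()] covariates z-standardized
#' with development-set statistics (stored inside the returned object, so
#' prediction needs no external state).
#'
#' \describe{
#'   \item{`"ann"`}{a single-hidden-layer feed-forward network (default 8
#'     logistic hidden units, linear output) fitted on the standardized
#'     target by [nnet::nnet()] in short optimization bursts, with early
#'     stopping on an internal 20\% validation split: training stops when
#'     the validation RMSE has not improved for `patience` bursts and the
#'     best weight vector seen is kept.}
#'   \item{`"svm"`}{epsilon-insensitive support vector regression with a
#'     radial basis kernel ([e1071::svm()]); the kernel width `gamma` and
#'     the cost are chosen by 5-fold cross-validated grid search over a
#'     small logarithmic grid, with seeded fold assignment.}
#' }
#'
#' Training is bit-reproducible: the same cohort, configuration and seed
#' give identical prediction vectors, and only the captured numeric state
#' (weights, support vectors, standardization statistics) is used at
#' prediction time.
#'
#' @param kind `"ann"` or `"svm"`.
#' @param cohort development cohort; every record must have `mgfr`.
#' @param config named list of hyperparameters overriding the defaults:
#'   for `"ann"` `hidden` (8), `decay` (1e-4), `step` (100 iterations per
#'   burst), `max_rounds` (30), `patience` (5), `val_fraction` (0.2); for
#'   `"svm"` `gamma_grid` (2^(-4, -2, 0)), `cost_grid` (1, 10, 100),
#'   `epsilon` (0.1), `folds` (5).
#' @param seed integer seed controlling the validation split, weight
#'   initialization and fold assignment.
#' @param min_n minimum development-cohort size (default 50).
#' @return An object of class `c("gfr_<kind>", "gfr_member")`.
#' @seealso [predict.gfr_member()], [write_member()], [gfr_ensemble()]
#' @export
train_member <- function(kind = c("ann", "svm"), cohort, config = list(),
                         seed = 1L, min_n = 50L) {
  kind <- match.arg(kind)
  cohort <- check_cohort(cohort, require_mgfr = TRUE)
  if (nrow(cohort) < min_n)
    stop("development cohort has ", nrow(cohort), " records; at least ",
         min_n, " are required", call. = FALSE)
  X <- build_features(cohort)
  y <- cohort$mgfr
  center <- vapply(X, mean, numeric(1))
  scale <- vapply(X, stats::sd, numeric(1))
  scale[scale == 0] <- 1            # constant covariate (e.g. one-sex cohort)
  Xs <- standardize_features(X, center, scale)
  y_center <- mean(y); y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1
  ys <- (y - y_center) / y_scale
  state <- switch(kind,
                  ann = fit_ann(Xs, ys, config, seed),
                  svm = fit_svm(Xs, ys, config, seed))
  member <- c(list(kind = kind,
                   x_center = center, x_scale = scale,
                   y_center = y_center, y_scale = y_scale,
                   seed = as.integer(seed)),
              state)
  structure(member, class = c(paste0("gfr_", kind), "gfr_member"))
}

fit_ann <- function(Xs, ys, config, seed) {
  hidden <- config$hidden %||% 8L
  decay <- config$decay %||% 1e-4
  step <- config$step %||% 100L
  max_rounds <- config$max_rounds %||% 30L
  patience <- config$patience %||% 5L
  val_fraction <- config$val_fraction %||% 0.2
  n <- nrow(Xs)
  set.seed(derive_seed(seed, 1L))
  n_val <- max(1L, round(val_fraction * n))
  val <- sample.int(n, n_val)
  tr <- setdiff(seq_len(n), val)
  n_wts <- (ncol(Xs) + 1L) * hidden + hidden + 1L
  wts <- stats::runif(n_wts, -0.5, 0.5)
  best_wts <- wts; best_rmse <- Inf; stale <- 0L
  for (round in seq_len(max_rounds)) {
    fit <- nnet::nnet(x = Xs[tr, , drop = FALSE], y = ys[tr], size = hidden,
                      linout = TRUE, Wts = wts, decay = decay,
                      maxit = step, trace = FALSE)
    wts <- fit$wts
    pred_val <- ann_forward(wts, hidden, Xs[val, , drop = FALSE])
    rmse <- sqrt(mean((pred_val - ys[val])^2))
    if (is.finite(rmse) && rmse < best_rmse - 1e-10) {
      best_rmse <- rmse; best_wts <- wts; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  if (!is.finite(best_rmse) || any(!is.finite(best_wts)))
    stop("ann member failed to converge", call. = FALSE)
  list(wts = best_wts, hidden = as.integer(hidden),
       val_rmse = best_rmse)
}

## forward pass through a single-hidden-layer net with logistic hidden
## units and a linear output, using nnet's weight layout
## (per hidden unit: bias then inputs; then output bias and hidden
## weights); nnet's C sigmoid saturates exactly outside |x| > 15 and the
## replication must too, or serialized predictions drift in the tails
ann_forward <- function(wts, hidden, Xs) {
  p <- ncol(Xs)
  W1 <- matrix(wts[seq_len((p + 1L) * hidden)], nrow = p + 1L)
  W2 <- wts[((p + 1L) * hidden + 1L):length(wts)]
  A <- cbind(1, Xs) %*% W1
  H <- stats::plogis(A)
  H[A > 15] <- 1
  H[A < -15] <- 0
  drop(cbind(1, H) %*% W2)
}

fit_svm <- function(Xs, ys, config, seed) {
  gamma_grid <- config$gamma_grid %||% 2^c(-4, -2, 0)
  cost_grid <- config$cost_grid %||% c(1, 10, 100)
  epsilon <- config$epsilon %||% 0.1
  n_folds <- config$folds %||% 5L
  n <- nrow(Xs)
  set.seed(derive_seed(seed, 2L))
  fold <- sample(rep_len(seq_len(n_folds), n))
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)
  cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    err <- vapply(seq_len(n_folds), function(k) {
      hold <- fold == k
      fit <- e1071::svm(x = Xs[!hold, , drop = FALSE], y = ys[!hold],
                        type = "eps-regression", kernel = "radial",
                        gamma = grid$gamma[g], cost = grid$cost[g],
                        epsilon = epsilon, scale = FALSE)
      mean((stats::predict(fit, Xs[hold, , drop = FALSE]) - ys[hold])^2)
    }, numeric(1))
    sqrt(mean(err))
  }, numeric(1))
  best <- which.min(cv_rmse)
  fit <- e1071::svm(x = Xs, y = ys, type = "eps-regression",
                    kernel = "radial", gamma = grid$gamma[best],
                    cost = grid$cost[best], epsilon = epsilon, scale = FALSE)
  list(sv = unname(as.matrix(fit$SV)), sv_coefs = drop(fit$coefs),
       rho = fit$rho, gamma = grid$gamma[best], cost = grid$cost[best],
       epsilon = epsilon, cv_rmse = cv_rmse[best])
}

## decision function of an RBF eps-regression machine on standardized inputs
svm_forward <- function(state, Xs) {
  sv <- state$sv
  d2 <- outer(rowSums(Xs^2), rowSums(sv^2), "+") - 2 * Xs %*% t(sv)
  K <- exp(-state$gamma * pmax(d2, 0))
  drop(K %*% state$sv_coefs) - state$rho
}

#' Predict GFR with a member model
#'
#' @param object a `gfr_member` (from [regression_member()],
#'   [train_member()] or [read_member()]).
#' @param cohort cohort data frame with `age`, `sex`, `scr`.
#' @param floor lower clip, ml/min/1.73 m\eqn{^2} (default 1): the flexible
#'   members can extrapolate to non-positive values, which would break the
#'   ratio-based accuracy metrics downstream.  The regression member never
#'   reaches the floor.
#' @param ... unused.
#' @return Numeric vector of estimated GFR, one per record.
#' @export
predict.gfr_member <- function(object, cohort, floor = 1, ...) {
  cohort <- check_cohort(cohort)
  if (nrow(cohort) == 0L) return(numeric(0))
  raw <- switch(object$kind,
    regression = estimate_gfr_regression(cohort$age, cohort$sex, cohort$scr,
                                         warn_age = FALSE),
    ann = ,
    svm = {
      if (is.null(object$wts) && is.null(object$sv))
        stop("member of kind '", object$kind, "' has no fitted state",
             call. = FALSE)
      Xs <- standardize_features(build_features(cohort),
                                 object$x_center, object$x_scale)
      z <- if (object$kind == "ann") ann_forward(object$wts, object$hidden, Xs)
           else svm_forward(object, Xs)
      z * object$y_scale + object$y_center
    },
    stop("unknown member kind: ", object$kind, call. = FALSE))
  pmax(raw, floor)
}

#' @export
print.gfr_member <- function(x, ...) {
  cat("GFR member model, kind:", x$kind, "\n")
  if (x$kind == "ann")
    cat("  hidden units:", x$hidden,
        " validation RMSE (standardized):", signif(x$val_rmse, 4), "\n")
  if (x$kind == "svm")
    cat("  gamma:", x$gamma, " cost:", x$cost,
        " support vectors:", nrow(x$sv), "\n")
  invisible(x)
}

#' Combine member models into an averaging ensemble
#'
#' The ensemble estimator is the element-wise arithmetic mean of its
#' members' predictions.  Averaging several approximately unbiased members
#' whose errors point in different directions reduces the spread of the
#' combined error, which is the precision gain the ensemble is built for.
#'
#' @param ... `gfr_member` objects, or a single list of them.
#' @return An object of class `"gfr_ensemble"`.
#' @export
#' @examples
#' ens <- gfr_ensemble(regression_member(), regression_member())
gfr_ensemble <- function(...) {
  members <- list(...)
  if (length(members) == 1L && !inherits(members[[1L]], "gfr_member"))
    members <- members[[1L]]
  if (length(members) == 0L)
    stop("an ensemble needs at least one member", call. = FALSE)
  ok <- vapply(members, inherits, logical(1), what = "gfr_member")
  if (!all(ok))
    stop("all ensemble members must be gfr_member objects", call. = FALSE)
  structure(list(members = members), class = "gfr_ensemble")
}

#' @rdname gfr_ensemble
#' @param object a `gfr_ensemble`.
#' @param cohort cohort data frame.
#' @param floor per-member lower clip, see [predict.gfr_member()].
#' @export
predict.gfr_ensemble <- function(object, cohort, floor = 1, ...) {
  preds <- vapply(object$members, predict, numeric(nrow(cohort)),
                  cohort = cohort, floor = floor)
  if (nrow(cohort) == 0L) return(numeric(0))
  if (length(object$members) == 1L) return(as.numeric(preds))
  rowMeans(matrix(preds, nrow = nrow(cohort)))
}

#' @export
print.gfr_ensemble <- function(x, ...) {
  kinds <- vapply(x$members, `[[`, character(1), "kind")
  cat("GFR averaging ensemble of", length(kinds), "members:",
      paste(kinds, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize and restore member models
#'
#' Members are stored as self-describing JSON; doubles are written as
#' 17-significant-digit decimal strings so that a restored member
#' reproduces its predictions bit-exactly.
#'
#' @param member a `gfr_member`.
#' @param path file path.
#' @return `write_member` returns `path` invisibly; `read_member` returns
#'   the restored `gfr_member`.
#' @export
write_member <- function(member, path) {
  stopifnot(inherits(member, "gfr_member"))
  x <- unclass(member)
  num <- c("x_center", "x_scale", "y_center", "y_scale", "wts", "val_rmse",
           "sv_coefs", "rho", "gamma", "cost", "epsilon", "cv_rmse")
  for (f in intersect(num, names(x))) x[[f]] <- num_to_chr(x[[f]])
  if (!is.null(x$sv)) x$sv <- apply(x$sv, 2L, num_to_chr)
  jsonlite::write_json(x, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_member
#' @export
read_member <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- x$kind
  if (!kind %in% c("regression", "ann", "svm"))
    stop("not a serialized gfr_member: ", path, call. = FALSE)
  num <- c("x_center", "x_scale", "y_center", "y_scale", "wts", "val_rmse",
           "sv_coefs", "rho", "gamma", "cost", "epsilon", "cv_rmse")
  for (f in intersect(num, names(x))) x[[f]] <- chr_to_num(x[[f]])
  if (!is.null(x$x_center)) names(x$x_center) <- feature_names
  if (!is.null(x$x_scale)) names(x$x_scale) <- feature_names
  if (!is.null(x$sv)) {
    x$sv <- apply(as.matrix(x$sv), 2L, chr_to_num)
    if (is.null(dim(x$sv))) x$sv <- matrix(x$sv, nrow = 1L)
  }
  if (!is.null(x$hidden)) x$hidden <- as.integer(x$hidden)
  if (!is.null(x$seed)) x$seed <- as.integer(x$seed)
  structure(x, class = c(paste0("gfr_", kind), "gfr_member"))
}
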