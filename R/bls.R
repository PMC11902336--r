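#' Configuration for a broad learning system
#'
#' A BLS is a flat network: the standardized inputs are projected through
#' `n_feature_groups` random linear feature maps of `nodes_per_group` nodes
#' each, the concatenated mapped features feed `n_enhancement` nonlinear
#' enhancement nodes (random orthonormalized weights, bounded activation), and
#' the output layer over `[mapped | enhancement]` is solved in closed form by
#' ridge regression. Defaults (10 x 10 mapped nodes, 100 enhancement nodes,
#' lambda = 2^-10, tanh) are the common desk-scale choices in the BLS
#' literature; all are exposed here.
#'
#' @param n_feature_groups Number of random feature-map groups (>= 1).
#' @param nodes_per_group Nodes per group (>= 1).
#' @param n_enhancement Enhancement nodes (>= 0).
#' @param ridge_lambda Ridge penalty (> 0).
#' @param activation Enhancement nonlinearity: `"tanh"` or `"sigmoid"`.
#' @param feature_map `"random"` linear maps, or `"identity"` to use the
#'   standardized inputs directly (the degenerate configuration in which the
#'   model is exactly ridge regression).
#' @param seed RNG seed for the random weights.
#' @param task `"classify"` (one-hot ridge, softmax scores) or `"regress"`.
#' @return A `bls_config` list.
#' @export
bls_config <- function(n_feature_groups = 10, nodes_per_group = 10,
                       n_enhancement = 100, ridge_lambda = 2^-10,
                       activation = c("tanh", "sigmoid"),
                       feature_map = c("random", "identity"),
                       seed = 1L, task = c("classify", "regress")) {
  activation <- match.arg(activation)
  feature_map <- match.arg(feature_map)
  task <- match.arg(task)
  stopifnot(n_feature_groups >= 1, nodes_per_group >= 1, n_enhancement >= 0)
  if (ridge_lambda <= 0)
    stop("`ridge_lambda` must be > 0 (the closed-form solve requires it)",
         call. = FALSE)
  structure(list(
    n_feature_groups = n_feature_groups, nodes_per_group = nodes_per_group,
    n_enhancement = n_enhancement, ridge_lambda = ridge_lambda,
    activation = activation, feature_map = feature_map,
    seed = as.integer(seed), task = task
  ), class = "bls_config")
}

as_matrix_x <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

# population (1/n) column standardization; zero-variance columns get scale 1
col_stats <- function(x) {
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  list(mu = mu, sd = sdev)
}

standardize <- function(x, st) sweep(sweep(x, 2, st$mu), 2, st$sd, "/")

act_fun <- function(name) switch(name, tanh = tanh,
                                 sigmoid = function(z) 1 / (1 + exp(-z)))

# random mapped-feature and enhancement weights for a given input width
bls_weights <- function(d, cfg) {
  withr::with_seed(cfg$seed, {
    wf <- if (cfg$feature_map == "identity") NULL else
      purrr::map(seq_len(cfg$n_feature_groups), function(g) {
        matrix(rnorm((d + 1) * cfg$nodes_per_group), nrow = d + 1) / sqrt(d + 1)
      })
    n_mapped <- if (cfg$feature_map == "identity") d else
      cfg$n_feature_groups * cfg$nodes_per_group
    we <- NULL
    if (cfg$n_enhancement > 0) {
      we <- matrix(rnorm((n_mapped + 1) * cfg$n_enhancement), nrow = n_mapped + 1)
      if (n_mapped + 1 >= cfg$n_enhancement) we <- qr.Q(qr(we))
    }
    list(wf = wf, we = we)
  })
}

mapped_nodes <- function(xs, model) {
  if (model$config$feature_map == "identity") return(xs)
  x1 <- cbind(xs, 1)
  do.call(cbind, purrr::map(model$wf, ~ x1 %*% .x))
}

enhancement_nodes <- function(z, model) {
  if (is.null(model$we)) return(NULL)
  act_fun(model$config$activation)(model$esc * (cbind(z, 1) %*% model$we))
}

design_matrix <- function(model, x, x_inc = NULL) {
  xs <- standardize(as_matrix_x(x), model$stats)
  z <- mapped_nodes(xs, model)
  a <- cbind(z, enhancement_nodes(z, model))
  if (!is.null(model$inc_stats)) {
    if (is.null(x_inc)) stop("model was fit with incremental features; `x_inc` required",
                             call. = FALSE)
    zi <- standardize(as_matrix_x(x_inc), model$inc_stats)
    a <- cbind(a, zi)
  }
  a
}

ridge_solve <- function(a, y, lambda) {
  ata <- crossprod(a)
  diag(ata) <- diag(ata) + lambda
  solve(ata, crossprod(a, y))
}

one_hot <- function(y) {
  f <- if (is.factor(y)) y else factor(y)
  if (nlevels(f) < 2) stop("classification needs at least two classes", call. = FALSE)
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Fit a broad learning system
#'
#' Builds the design `A = [mapped | enhancement]` from the standardized
#' inputs and solves the ridge normal equations
#' `W = (A'A + lambda I)^-1 A'Y` exactly. Classification targets are one-hot
#' encoded; scores stay linear (probabilities are produced by a softmax at
#' prediction time). Fits with the same seed are bit-identical.
#'
#' @param x Numeric matrix or data frame of predictors (no missing values).
#' @param y Targets: factor/vector with >= 2 classes, or numeric for
#'   regression.
#' @param config A [bls_config()].
#' @return A fitted `bls` object.
#' @examples
#' cfg <- bls_config(task = "regress", seed = 2)
#' fit <- bls_fit(matrix(rnorm(200), 50), rnorm(50), cfg)
#' predict(fit, matrix(rnorm(40), 10))
#' @export
bls_fit <- function(x, y, config = bls_config()) {
  x <- as_matrix_x(x)
  if (anyNA(x) || any(!is.finite(x))) stop("`x` contains missing or non-finite values",
                                           call. = FALSE)
  stats <- col_stats(x)
  model <- structure(list(config = config, stats = stats,
                          feature_names = colnames(x)), class = "bls")
  ww <- bls_weights(ncol(x), config)
  model$wf <- ww$wf
  model$we <- ww$we
  xs <- standardize(x, stats)
  z <- mapped_nodes(xs, model)
  model$esc <- 1
  if (!is.null(model$we)) {
    pre <- cbind(z, 1) %*% model$we
    m <- max(abs(pre))
    model$esc <- if (m > 0) 0.8 / m else 1
  }
  ymat <- if (config$task == "classify") {
    model$levels <- levels(factor(y))
    one_hot(y)
  } else {
    model$y_range <- range(as.numeric(y))
    matrix(as.numeric(y), ncol = 1)
  }
  a <- cbind(z, enhancement_nodes(z, model))
  model$w <- ridge_solve(a, ymat, config$ridge_lambda)
  model$n_train <- nrow(x)
  model
}

#' Refit a BLS with incremental input features
#'
#' Appends `x_inc` (centred and scaled by its own population statistics, no
#' bias, identity-mapped so a zero increment provably leaves the model
#' unchanged) as an extra mapped-feature group, keeps the original random
#' maps fixed, and re-solves the output weights in closed form over the
#' augmented design — exactly equal to a from-scratch ridge solve on
#' `[A | X_inc]`.
#'
#' @param model A fitted `bls` (without incremental features).
#' @param x The original training inputs (row-aligned with `x_inc`).
#' @param x_inc Incremental feature matrix.
#' @param y Training targets (as in [bls_fit()]).
#' @return A fitted `bls` whose `predict()` requires `x_inc`.
#' @export
bls_fit_incremental <- function(model, x, x_inc, y) {
  stopifnot(inherits(model, "bls"))
  x <- as_matrix_x(x)
  x_inc <- as_matrix_x(x_inc)
  if (nrow(x) != nrow(x_inc))
    stop("`x` and `x_inc` must have the same number of rows", call. = FALSE)
  base <- model
  base$inc_stats <- NULL
  a_old <- design_matrix(base, x)
  st <- col_stats(x_inc)
  model$inc_stats <- st
  zi <- standardize(x_inc, st)
  ymat <- if (model$config$task == "classify") {
    one_hot(factor(y, levels = model$levels))
  } else {
    model$y_range <- range(as.numeric(y))
    matrix(as.numeric(y), ncol = 1)
  }
  model$w <- ridge_solve(cbind(a_old, zi), ymat, model$config$ridge_lambda)
  model
}

#' Predict from a fitted BLS
#'
#' @param object A fitted `bls`.
#' @param x New data with the training columns.
#' @param x_inc Incremental features (required iff the model was refit with
#'   [bls_fit_incremental()]).
#' @param type `"score"` (linear outputs), `"prob"` (softmax over class
#'   scores), `"class"`, or `"response"` (regression output; alias of score).
#' @param ... Unused.
#' @return Matrix of scores/probabilities, factor of classes, or numeric
#'   vector for regression.
#' @export
predict.bls <- function(object, x, x_inc = NULL,
                        type = c("score", "prob", "class", "response"), ...) {
  type <- match.arg(type)
  x <- as_matrix_x(x)
  if (!is.null(object$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), object$feature_names))
    stop("prediction columns do not match the training registry", call. = FALSE)
  scores <- design_matrix(object, x, x_inc) %*% object$w
  if (object$config$task == "regress" || type %in% c("score", "response"))
    return(if (ncol(scores) == 1) drop(scores) else scores)
  p <- softmax_rows(scores)
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, ties.method = "first")], levels = object$levels)
}

# numerically stable row softmax
softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

#' @export
print.bls <- function(x, ...) {
  cfg <- x$config
  n_mapped <- if (cfg$feature_map == "identity") length(x$stats$mu)
              else cfg$n_feature_groups * cfg$nodes_per_group
  cat(sprintf("<bls %s> %d mapped + %d enhancement nodes, lambda = %.3g%s\n",
              cfg$task, n_mapped, cfg$n_enhancement, cfg$ridge_lambda,
              if (!is.null(x$inc_stats))
                sprintf(", +%d incremental", length(x$inc_stats$mu)) else ""))
  invisible(x)
}

#' @describeIn bls_fit Output weights as a tibble (one row per design column
#'   and output).
#' @param x A fitted `bls` (for `tidy`/`glance`).
#' @param ... Unused.
#' @export
tidy.bls <- function(x, ...) {
  w <- x$w
  tibble::tibble(
    node = rep(seq_len(nrow(w)), ncol(w)),
    output = rep(colnames(w) %||% as.character(seq_len(ncol(w))),
                 each = nrow(w)),
    weight = as.vector(w)
  )
}

#' @describeIn bls_fit One-row model summary.
#' @export
glance.bls <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    task = cfg$task,
    n_train = x$n_train %||% NA_integer_,
    n_mapped = if (cfg$feature_map == "identity") length(x$stats$mu)
               else cfg$n_feature_groups * cfg$nodes_per_group,
    n_enhancement = cfg$n_enhancement,
    n_incremental = if (is.null(x$inc_stats)) 0L else length(x$inc_stats$mu),
    ridge_lambda = cfg$ridge_lambda,
    seed = cfg$seed
  )
}

#' Save / load a fitted BLS
#'
#' Round-trips the full model object (config plus all weight matrices);
#' reloaded models reproduce predictions bit-exactly.
#'
#' @param model A fitted `bls`.
#' @param path File path.
#' @return `bls_save()` the path invisibly; `bls_load()` the model.
#' @export
bls_save <- function(model, path) {
  stopifnot(inherits(model, "bls"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname bls_save
#' @export
bls_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bls"))
  model
}
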