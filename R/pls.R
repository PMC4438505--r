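# Partial least squares for a binary outcome (PLS1 / PLS-DA via NIPALS on a
# 0/1-coded response), with VIP (variable importance in projection) scores.
# This is the panel-selection engine of the pipeline: features are ranked by
# VIP averaged over cross-validation fits, and genes with mean VIP > 1 form
# the panel. Predictors are autoscaled (centred, unit variance); constant
# columns get scale 1.

#' Fit a PLS discriminant model
#'
#' NIPALS PLS with a single centred 0/1 response. The returned object
#' predicts a continuous discriminant score (larger = more relapse-like)
#' via [predict()].
#'
#' @param x Numeric sample-by-gene matrix (complete; see
#'   [impute_missing()]).
#' @param y Response: a factor/character of `"relapse"`/`"control"` or a
#'   0/1 numeric vector (1 = relapse).
#' @param ncomp Number of latent components; capped at
#'   `min(n - 1, ncol(x))` (default 2).
#' @return An object of class `meth_pls` with elements `weights`,
#'   `loadings`, `qs`, `scores`, `coef`, `vip`, `ncomp` and the scaling
#'   parameters.
#' @export
pls_fit <- function(x, y, ncomp = 2) {
  x <- as.matrix(x)
  y01 <- to_binary(y)
  if (length(y01) != nrow(x)) abort("length(y) must match nrow(x)")
  if (length(unique(y01)) < 2) abort("both classes must be present")
  n <- nrow(x)
  p <- ncol(x)
  a_max <- max(1L, min(ncomp, n - 1L, p))
  x_center <- colMeans(x)
  x_scale <- apply(x, 2, sd)
  x_scale[x_scale == 0 | is.na(x_scale)] <- 1
  xs <- scale(x, center = x_center, scale = x_scale)
  y_mean <- mean(y01)
  yc <- y01 - y_mean
  W <- P <- matrix(0, p, a_max)
  Tm <- matrix(0, n, a_max)
  q <- numeric(a_max)
  xd <- xs
  yd <- yc
  a_used <- 0L
  for (a in seq_len(a_max)) {
    w <- crossprod(xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- xd %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- crossprod(xd, t_a)[, 1] / tt
    q_a <- sum(yd * t_a) / tt
    xd <- xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) abort("PLS found no usable component")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  # regression coefficients on the scaled predictors
  bmat <- W %*% solve(crossprod(P, W), diag(a_used)) %*% q
  fitted <- y_mean + (xs %*% bmat)[, 1]
  structure(
    list(
      weights = W, loadings = P, qs = q, scores = Tm, coef = bmat[, 1],
      x_center = x_center, x_scale = x_scale, y_mean = y_mean,
      ncomp = a_used, genes = colnames(x), n = n,
      fitted = fitted, y = y01,
      vip = setNames(pls_vip(W, Tm, q), colnames(x))
    ),
    class = "meth_pls"
  )
}

# VIP_j = sqrt( p * sum_a ss_a * w_ja^2 / sum_a ss_a ), ss_a = q_a^2 t_a't_a
# (weights are unit-norm per component, so sum_j VIP_j^2 = p)
pls_vip <- function(W, Tm, q) {
  ss <- q^2 * colSums(Tm^2)
  p <- nrow(W)
  vip <- sqrt(p * as.numeric(W^2 %*% ss) / sum(ss))
  names(vip) <- rownames(W)
  vip
}

to_binary <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c(.POS, .NEG))
    if (length(bad) > 0) abort(paste("unknown labels:", toString(bad)))
    return(as.numeric(y == .POS))
  }
  if (!all(y %in% c(0, 1))) abort("numeric response must be 0/1")
  as.numeric(y)
}

#' @export
predict.meth_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$genes) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$genes, drop = FALSE]
  }
  xs <- scale(newdata, center = object$x_center, scale = object$x_scale)
  object$y_mean + (xs %*% object$coef)[, 1]
}

#' @export
print.meth_pls <- function(x, ...) {
  cat(sprintf(
    "<meth_pls> %d samples, %d genes, %d component(s)\n",
    x$n, length(x$coef), x$ncomp
  ))
  invisible(x)
}

#' Tidy a PLS fit
#'
#' @param x A `meth_pls` object.
#' @param ... Unused.
#' @return One row per gene: `gene_id`, component weights, `coefficient`
#'   (on scaled predictors) and `vip`.
#' @export
tidy.meth_pls <- function(x, ...) {
  w <- x$weights
  colnames(w) <- paste0("weight_c", seq_len(ncol(w)))
  bind_cols(
    tibble(gene_id = x$genes),
    as_tibble(w),
    tibble(coefficient = unname(x$coef), vip = unname(x$vip))
  )
}

#' Glance at a PLS fit
#'
#' @param x A `meth_pls` object.
#' @param ... Unused.
#' @return A one-row tibble: sample and gene counts, components used, and
#'   in-sample score/response correlation squared.
#' @export
glance.meth_pls <- function(x, ...) {
  tibble(
    n = x$n, n_genes = length(x$coef), ncomp = x$ncomp,
    r_squared = stats::cor(x$fitted, x$y)^2,
    auc_resub = auc_rank(x$fitted, x$y)
  )
}
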