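# Phylogenetic linear regression by generalized least squares.
#
# The residual covariance is sigma2 * V(lambda) with
#   V(lambda) = lambda * V + (1 - lambda) * diag(V),
# V the Brownian-motion covariance of the tree and lambda Pagel's lambda:
# lambda = 1 is pure Brownian motion, lambda = 0 star-tree independence.
# The system is solved by Cholesky whitening (never an explicit inverse):
# with V(lambda) = R'R, regress R'^-1 y on R'^-1 X by QR.

LAMBDA_GRID <- seq(0, 1, by = 0.05)

# Cholesky of V(lambda), failing loudly on non-PD input
chol_vlambda <- function(V, lambda) {
  Vl <- lambda * V + (1 - lambda) * diag(diag(V), nrow(V))
  R <- tryCatch(chol(Vl), error = function(e)
    abort_fmt("covariance V(lambda = %.2f) is not positive definite: %s",
              lambda, conditionMessage(e)))
  R
}

# whitening context reusable across many response vectors
make_whitener <- function(X, V, lambda) {
  R <- chol_vlambda(V, lambda)
  Xw <- backsolve(R, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) abort_fmt("design matrix is rank deficient")
  list(R = R, qrX = qrX, logdet = 2 * sum(log(diag(R))),
       lambda = lambda, n = nrow(X), p = ncol(X))
}

# GLS fit of one response under a prepared whitener
whitened_fit <- function(w, y) {
  yw <- backsolve(w$R, y, transpose = TRUE)
  beta <- qr.coef(w$qrX, yw)
  rss <- sum(qr.resid(w$qrX, yw)^2)
  loglik <- -0.5 * (w$n * (log(2 * pi) + log(rss / w$n) + 1) + w$logdet)
  list(beta = beta, rss = rss, loglik = loglik)
}

#' Phylogenetic linear regression (generalized least squares)
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * V(lambda))`, where `V` is a
#' Brownian-motion covariance from a phylogeny and `V(lambda) = lambda V +
#' (1 - lambda) diag(V)` interpolates between full phylogenetic covariance
#' (`lambda = 1`) and independence. With `lambda = "ml"`, Pagel's lambda is
#' profiled over a 21-point grid on \[0, 1\].
#'
#' @param y Numeric response (one standardized gene's copy numbers,
#'   ordered as the rows of `V`).
#' @param X Design matrix with intercept (same row order).
#' @param V Phylogenetic covariance matrix, e.g. from [bm_covariance()].
#' @param lambda `"fixed"` (Brownian motion at `lambda_fixed`) or `"ml"`.
#' @param lambda_fixed Value used when `lambda = "fixed"`.
#' @return Object of class `phylo_lm`: coefficients, standard errors,
#'   t statistics, two-sided p-values (Student-t, `n - p` df), `sigma2`,
#'   `lambda`, log-likelihood, residuals and fitted values on the original
#'   scale.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' V <- bm_covariance(tr)
#' X <- cbind(1, c(0, 0, 1, 1))
#' phylo_lm(c(1, 2, 3, 4), X, V)
#' @export
phylo_lm <- function(y, X, V, lambda = c("fixed", "ml"), lambda_fixed = 1) {
  lambda <- match.arg(lambda)
  y <- as.numeric(y)
  X <- as.matrix(X)
  V <- as.matrix(V)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    abort_fmt("dimensions of y (%d), X (%d rows), V (%d x %d) disagree",
              n, nrow(X), nrow(V), ncol(V))
  }
  if (max(abs(V - t(V))) > 1e-8) abort_fmt("V must be symmetric")
  p <- ncol(X)
  if (n <= p) abort_fmt("need more observations than parameters")

  if (lambda == "fixed") {
    w <- make_whitener(X, V, lambda_fixed)
    fit <- whitened_fit(w, y)
    lam_hat <- lambda_fixed
  } else {
    best <- NULL
    for (lam in LAMBDA_GRID) {
      w_try <- make_whitener(X, V, lam)
      f_try <- whitened_fit(w_try, y)
      if (is.null(best) || f_try$loglik > best$fit$loglik) {
        best <- list(w = w_try, fit = f_try, lam = lam)
      }
    }
    w <- best$w; fit <- best$fit; lam_hat <- best$lam
  }
  sigma2 <- fit$rss / (n - p)
  XtX_inv <- chol2inv(qr.R(w$qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- fit$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  fitted <- drop(X %*% fit$beta)
  cn <- colnames(X)
  if (is.null(cn)) cn <- c("(Intercept)", paste0("x", seq_len(p - 1L)))[seq_len(p)]
  names(fit$beta) <- names(se) <- names(tval) <- names(pval) <- cn
  structure(list(
    coefficients = fit$beta, se = se, t = tval, p = pval,
    sigma2 = sigma2, lambda = lam_hat, lambda_mode = lambda,
    loglik = fit$loglik, df.residual = n - p,
    vcov = sigma2 * XtX_inv,
    fitted.values = fitted, residuals = y - fitted,
    y = y, X = X), class = "phylo_lm")
}

#' @export
print.phylo_lm <- function(x, ...) {
  cat(sprintf("Phylogenetic linear model (lambda = %.2f%s)\n", x$lambda,
              if (x$lambda_mode == "ml") ", ML" else ", fixed"))
  print(round(cbind(Estimate = x$coefficients, `Std.Error` = x$se,
                    t = x$t, `p` = x$p), 4))
  invisible(x)
}

#' @export
summary.phylo_lm <- function(object, ...) {
  structure(list(coefficients = cbind(Estimate = object$coefficients,
                                      `Std. Error` = object$se,
                                      `t value` = object$t,
                                      `Pr(>|t|)` = object$p),
                 sigma2 = object$sigma2, lambda = object$lambda,
                 loglik = object$loglik, df.residual = object$df.residual),
            class = "summary.phylo_lm")
}

#' @export
print.summary.phylo_lm <- function(x, ...) {
  cat("Phylogenetic linear model\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nsigma2: %.4g  lambda: %.2f  logLik: %.3f  df: %d\n",
              x$sigma2, x$lambda, x$loglik, x$df.residual))
  invisible(x)
}

#' @export
coef.phylo_lm <- function(object, ...) object$coefficients

#' @export
vcov.phylo_lm <- function(object, ...) object$vcov

#' @export
residuals.phylo_lm <- function(object, ...) object$residuals

#' @export
fitted.phylo_lm <- function(object, ...) object$fitted.values

#' @export
logLik.phylo_lm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2,
            class = "logLik")
}

#' @export
predict.phylo_lm <- function(object, newX = NULL, ...) {
  if (is.null(newX)) return(object$fitted.values)
  drop(as.matrix(newX) %*% object$coefficients)
}

# Vectorized engine: fit many responses (columns of Y) under one design,
# profiling lambda per response over the shared grid. Whitening contexts
# are prepared once per lambda and reused across responses.
phylo_lm_many <- function(Y, X, V, lambda = c("fixed", "ml"),
                          lambda_fixed = 1) {
  lambda <- match.arg(lambda)
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(X)
  grid <- if (lambda == "fixed") lambda_fixed else LAMBDA_GRID
  ws <- lapply(grid, function(l) make_whitener(X, V, l))
  G <- ncol(Y)
  # loglik per (lambda, gene)
  stats_for <- function(w) {
    Yw <- backsolve(w$R, Y, transpose = TRUE)
    B <- qr.coef(w$qrX, Yw)
    rss <- colSums(qr.resid(w$qrX, Yw)^2)
    ll <- -0.5 * (n * (log(2 * pi) + log(rss / n) + 1) + w$logdet)
    list(B = B, rss = rss, ll = ll, XtX_inv = chol2inv(qr.R(w$qrX)))
  }
  per_lam <- lapply(ws, stats_for)
  ll_mat <- do.call(rbind, lapply(per_lam, `[[`, "ll"))   # grid x G
  pick <- apply(ll_mat, 2, which.max)
  beta <- se <- matrix(NA_real_, p, G)
  lam_hat <- numeric(G)
  for (gi in seq_along(grid)) {
    sel <- which(pick == gi)
    if (!length(sel)) next
    st <- per_lam[[gi]]
    beta[, sel] <- st$B[, sel, drop = FALSE]
    s2 <- st$rss[sel] / (n - p)
    se[, sel] <- sqrt(outer(diag(st$XtX_inv), s2))
    lam_hat[sel] <- grid[gi]
  }
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  list(beta = beta, se = se, t = tval, p = pval, lambda = lam_hat,
       loglik = ll_mat[cbind(pick, seq_len(G))])
}
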