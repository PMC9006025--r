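# Cumulative-link (proportional-odds) mixed model with a single random
# intercept, fitted by maximum likelihood with Gauss-Hermite quadrature
# over the random effect. This is the "global participant" random
# structure; it is what the ordinal gesture-space ladder uses.

gauss_hermite <- function(n) {
  # nodes/weights for the probabilists' rule via the Golub-Welsch
  # eigen-decomposition of the Jacobi matrix (physicists' rule rescaled)
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2 * sqrt(pi)
  # convert to N(0,1) expectation rule: E[f(u)] ~ sum w_i f(x_i sqrt(2)) / sqrt(pi)
  list(nodes = x * sqrt(2), weights = w / sqrt(pi))
}

clmm_nll <- function(par, y, X, group, J, gh) {
  k <- ncol(X)
  theta <- if (J == 2) par[1]
           else par[1] + c(0, cumsum(exp(par[2:(J - 1)])))
  beta <- if (k) par[(J - 1) + seq_len(k)] else numeric(0)
  sigma_u <- exp(par[length(par)])
  eta <- if (k) as.numeric(X %*% beta) else numeric(length(y))
  # per-group log-likelihood at each quadrature node, vectorized over
  # observations; groups combined on the log scale for stability
  G <- nlevels(group)
  Q <- length(gh$nodes)
  ls <- matrix(0, G, Q)
  for (q in seq_len(Q)) {
    e <- eta + sigma_u * gh$nodes[q]
    upper <- ifelse(y == J, 1, plogis(theta[pmin(y, J - 1)] - e))
    lower <- ifelse(y == 1, 0, plogis(theta[pmax(y - 1, 1)] - e))
    ls[, q] <- rowsum(log(pmax(upper - lower, 1e-12)), group)
  }
  m <- apply(ls, 1, max)
  lik <- rowSums(exp(ls - m) * rep(gh$weights, each = G))
  -sum(m + log(pmax(lik, 1e-300)))
}

#' Cumulative-link mixed model (logit link, one random intercept)
#'
#' Proportional-odds model `logit P(Y <= j) = theta_j - X beta - u_g`,
#' `u_g ~ N(0, sigma^2)`, fitted by maximum likelihood with Gauss-Hermite
#' quadrature (default 15 nodes) over the grouping factor's random
#' intercept. Ordinal categories with zero observations are merged into
#' their inner neighbour with a warning.
#'
#' @param y ordered factor response.
#' @param X fixed-effects model matrix WITHOUT intercept (may have zero
#'   columns for the null model).
#' @param group grouping factor for the random intercept.
#' @param n_quad quadrature nodes.
#' @return object of class `clmm_fit`: `theta` (thresholds), `beta`,
#'   `sigma_u`, `logLik`, `df`, `vcov_beta`, `z` (Wald z per beta),
#'   `convergence`.
#' @export
clmm_fit <- function(y, X, group, n_quad = 15L) {
  y <- droplevels(as.ordered(y))
  tab <- table(y)
  if (any(tab == 0)) {
    warning("empty ordinal categories merged")
    y <- droplevels(y)
  }
  J <- nlevels(y)
  if (J < 2) stop("response has fewer than 2 observed categories")
  yi <- as.integer(y)
  X <- as.matrix(X)
  k <- ncol(X)
  group <- factor(group)
  gh <- gauss_hermite(n_quad)
  # start values: logit of cumulative proportions, beta 0, sigma 0.5
  cum <- cumsum(prop.table(table(yi)))[seq_len(J - 1)]
  th0 <- qlogis(pmin(pmax(cum, 0.01), 0.99))
  par0 <- c(th0[1], if (J > 2) log(pmax(diff(th0), 0.05)),
            rep(0, k), log(0.5))
  fit <- optim(par0, clmm_nll, y = yi, X = X, group = group, J = J,
               gh = gh, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500))
  np <- length(fit$par)
  theta <- fit$par[1] + if (J > 2) c(0, cumsum(exp(fit$par[2:(J - 1)])))
                        else 0
  beta <- if (k) fit$par[(J - 1) + seq_len(k)] else numeric(0)
  names(beta) <- colnames(X)
  vcov_all <- tryCatch(solve(fit$hessian), error = function(e)
    matrix(NA_real_, np, np))
  vb <- if (k) vcov_all[(J - 1) + seq_len(k), (J - 1) + seq_len(k),
                        drop = FALSE] else matrix(0, 0, 0)
  z <- if (k) beta / sqrt(pmax(diag(vb), 1e-12)) else numeric(0)
  structure(list(theta = unname(theta), beta = beta,
                 sigma_u = unname(exp(fit$par[np])),
                 logLik = -fit$value,
                 df = np, vcov_beta = vb, z = z, n = length(yi),
                 convergence = fit$convergence == 0),
            class = "clmm_fit")
}

#' @export
print.clmm_fit <- function(x, ...) {
  cat(sprintf("<clmm_fit: logLik %.2f, sigma_u %.3f, df %d>\n", x$logLik,
              x$sigma_u, x$df))
  if (length(x$beta)) {
    for (i in seq_along(x$beta))
      cat(sprintf("  %s: %.4f (z = %.2f)\n", names(x$beta)[i], x$beta[i],
                  x$z[i]))
  }
  invisible(x)
}

#' Ordinal ladder for McNeillian gesture space
#'
#' The polynomial comparison ladder with a cumulative-link family:
#' random-intercept-only null vs linear vs quadratic blur-grade models,
#' reporting likelihood-ratio statistics and Wald z-values (the ordinal
#' analogue of the gaussian ladder's chi-square and t).
#'
#' @param space_table data.frame with columns `mcneillian_space` (ordered
#'   factor or character with the standard levels), `blur_grade` and
#'   `participant_id`.
#' @param alpha significance level for both comparisons.
#' @param n_quad quadrature nodes passed to [clmm_fit()].
#' @return object of class `ordinal_ladder`: `lr` (quad vs null), `df`,
#'   `p`, `quad_vs_linear`, `significant`, `z` (quadratic-model Wald z),
#'   `fits`.
#' @export
ordinal_space_test <- function(space_table, alpha = 0.05, n_quad = 15L) {
  y <- space_table$mcneillian_space
  if (!is.ordered(y))
    y <- factor(y, levels = MCNEILL_LEVELS, ordered = TRUE)
  g <- factor(space_table$participant_id)
  bg <- as.numeric(space_table$blur_grade)
  P <- poly(bg, 2)
  fits <- list(
    null = clmm_fit(y, matrix(numeric(0), length(y), 0), g, n_quad),
    linear = clmm_fit(y, P[, 1, drop = FALSE], g, n_quad),
    quad = clmm_fit(y, P, g, n_quad))
  lr_main <- 2 * (fits$quad$logLik - fits$null$logLik)
  df_main <- fits$quad$df - fits$null$df
  lr_lin <- 2 * (fits$quad$logLik - fits$linear$logLik)
  df_lin <- fits$quad$df - fits$linear$df
  p_main <- pchisq(max(lr_main, 0), df_main, lower.tail = FALSE)
  p_lin <- pchisq(max(lr_lin, 0), df_lin, lower.tail = FALSE)
  structure(list(lr = lr_main, df = df_main, p = p_main,
                 quad_vs_linear = list(lr = lr_lin, df = df_lin,
                                       p = p_lin),
                 significant = p_main < alpha && p_lin < alpha,
                 z = fits$quad$z, fits = fits, alpha = alpha),
            class = "ordinal_ladder")
}

#' @export
print.ordinal_ladder <- function(x, ...) {
  cat(sprintf("Ordinal quadratic vs null:   LR(%d) = %.3f, p = %.4g\n",
              x$df, x$lr, x$p))
  cat(sprintf("Ordinal quadratic vs linear: LR(%d) = %.3f, p = %.4g\n",
              x$quad_vs_linear$df, x$quad_vs_linear$lr,
              x$quad_vs_linear$p))
  invisible(x)
}
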