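#' Fit a negative binomial count regression, with optional host random intercept
#'
#' `nb_fit()` is the modelling engine of the package. It fits a negative
#' binomial regression with log link, `Var(y) = mu + mu^2/theta`, to
#' non-negative integer responses. The fixed-effects model (`y ~ x`) is fitted
#' by iteratively reweighted least squares for the coefficients alternating
#' with maximum-likelihood updates of the dispersion `theta`. A single random
#' intercept may be requested lme4-style (`y ~ x + (1 | host)`); the marginal
#' likelihood then integrates a normal random intercept per group by adaptive
#' Gauss-Hermite quadrature (`nAGQ` points; 1 gives the Laplace
#' approximation), and the random-intercept standard deviation `sigma_b` is
#' reported.
#'
#' Standard errors come from the Fisher information `X'WX` at the optimum for
#' the fixed-effects model, and from the numerically differentiated observed
#' information of the marginal likelihood for the mixed model. A fit whose
#' `sigma_b` collapses to the lower bound (or that has one observation per
#' group, where `sigma_b` is unidentifiable) is flagged `boundary` and
#' reported with `sigma_b = 0`.
#'
#' @param formula Model formula; the response must be counts. At most one
#'   random-intercept term of the form `(1 | group)` is supported.
#' @param data Data frame holding the variables.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature points (mixed
#'   model only).
#' @param theta_bounds Lower and upper bounds for the dispersion estimate.
#' @param tol Relative convergence tolerance on the log-likelihood.
#' @param max_iter Maximum number of iterations.
#' @return An object of class `"nb_fit"` with methods `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `fitted`, `predict`, `residuals` and
#'   `simulate`.
#' @examples
#' d <- data.frame(x = rep(0:1, each = 20))
#' d$y <- rnbinom(40, mu = exp(1 + 0.8 * d$x), size = 2)
#' fit <- nb_fit(y ~ x, d)
#' summary(fit)
#' @export
nb_fit <- function(formula, data, nAGQ = 7, theta_bounds = c(1e-3, 1e6),
                   tol = 1e-6, max_iter = 200) {
  parsed <- split_random_term(formula)
  mf <- stats::model.frame(parsed$fixed, data = data)
  y <- stats::model.response(mf)
  assert_that(is.numeric(y) && all(y >= 0) && all(y == round(y)),
              "response must be non-negative integer counts")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (is.null(parsed$group)) {
    core <- fit_nb_glm_core(y, X, theta_bounds = theta_bounds,
                            tol = tol, max_iter = max_iter)
  } else {
    assert_that(parsed$group %in% colnames(data),
                sprintf("grouping variable '%s' not in data", parsed$group))
    group <- data[[parsed$group]]
    if (nrow(mf) < nrow(data))
      group <- group[match(rownames(mf), rownames(data))]
    core <- fit_nb_glmm_core(y, X, group, nAGQ = nAGQ,
                             theta_bounds = theta_bounds,
                             tol = tol, max_iter = max_iter)
  }
  core$call <- match.call()
  core$formula <- formula
  core$fixed_terms <- stats::delete.response(attr(mf, "terms"))
  class(core) <- "nb_fit"
  core
}

# Split an lme4-style formula into its fixed part and the name of the single
# random-intercept grouping variable (or NULL).
#' @noRd
split_random_term <- function(formula) {
  bars <- list()
  walk <- function(e) {
    if (is.call(e)) {
      if (identical(e[[1]], as.name("(")) && is.call(e[[2]]) &&
          identical(e[[2]][[1]], as.name("|"))) {
        bars[[length(bars) + 1]] <<- e[[2]]
      } else lapply(as.list(e)[-1], walk)
    }
    invisible(NULL)
  }
  walk(formula[[3]])
  if (length(bars) == 0)
    return(list(fixed = formula, group = NULL))
  assert_that(length(bars) == 1, "only one random-intercept term is supported")
  bar <- bars[[1]]
  assert_that(identical(bar[[2]], 1) || identical(bar[[2]], as.name("1")),
              "only random intercepts '(1 | group)' are supported")
  group <- deparse(bar[[3]])
  txt <- paste(deparse(formula), collapse = " ")
  fixed_txt <- gsub("\\+?\\s*\\(\\s*1\\s*\\|[^)]*\\)", "", txt)
  fixed <- stats::as.formula(fixed_txt, env = environment(formula))
  list(fixed = fixed, group = group)
}

# -- fixed-effects fitter ----------------------------------------------------

#' @noRd
fit_nb_glm_core <- function(y, X, theta_bounds = c(1e-3, 1e6),
                            tol = 1e-6, max_iter = 200, profile_tol = 1e-9) {
  n <- length(y); p <- ncol(X)
  assert_that(nrow(X) == n, "length(y) must equal nrow(X)")
  assert_that(qr(X)$rank == p, "design matrix is not full rank")
  if (all(y == 0)) stop("degenerate response: all counts are zero", call. = FALSE)

  lb <- log(theta_bounds[1]); ub <- log(theta_bounds[2])
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  m <- mean(y); v <- stats::var(y)
  theta <- min(max(m^2 / max(v - m, m * 0.1), theta_bounds[1]), theta_bounds[2])

  loglik <- -Inf; converged <- FALSE; it <- 0
  beta <- rep(0, p)
  repeat {
    it <- it + 1
    # IRLS for beta at fixed theta
    for (k in 1:25) {
      W <- mu / (1 + mu / theta)
      zwork <- eta + (y - mu) / mu
      fit <- stats::lm.wfit(X, zwork, W)
      beta_new <- fit$coefficients
      eta <- pmin(pmax(drop(X %*% beta_new), -40), 40)
      mu <- exp(eta)
      if (all(abs(beta_new - beta) < 1e-10 * (abs(beta) + 1e-3))) {
        beta <- beta_new; break
      }
      beta <- beta_new
    }
    # ML update of theta (profile over log theta)
    opt <- stats::optimize(function(lt) -sum(dnbinom(y, size = exp(lt),
                                                     mu = mu, log = TRUE)),
                           interval = c(lb, ub), tol = profile_tol)
    theta <- exp(opt$minimum)
    ll_new <- -opt$objective
    if (is.finite(loglik) &&
        abs(ll_new - loglik) < tol * (abs(loglik) + 1e-8)) {
      loglik <- ll_new; converged <- TRUE; break
    }
    loglik <- ll_new
    if (it >= max_iter) break
  }

  W <- mu / (1 + mu / theta)
  XtWX <- crossprod(X * sqrt(W))
  vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  theta_boundary <- theta <= theta_bounds[1] * 1.0001 ||
    theta >= theta_bounds[2] * 0.9999

  list(coefficients = setNames(drop(beta), colnames(X)), se = se, vcov = vc,
       theta = theta, sigma_b = NA_real_, logLik = loglik,
       converged = converged, boundary = theta_boundary, iterations = it,
       fitted = mu, y = y, X = X, group = NULL, nAGQ = NA_integer_)
}

# -- mixed-model fitter ------------------------------------------------------

# Gauss-Hermite nodes/weights (weight exp(-x^2)) by Golub-Welsch.
#' @noRd
gh_rule <- function(k) {
  if (k == 1) return(list(z = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(k - 1) / 2)
  J <- diag(0, k)
  J[cbind(seq_len(k - 1), 2:k)] <- off
  J[cbind(2:k, seq_len(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(z = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

#' @noRd
fit_nb_glmm_core <- function(y, X, group, nAGQ = 7,
                             theta_bounds = c(1e-3, 1e6),
                             tol = 1e-6, max_iter = 200) {
  n <- length(y); p <- ncol(X)
  assert_that(nrow(X) == n && length(group) == n,
              "y, X and group must have matching lengths")
  group <- as.character(group)
  assert_that(length(unique(group)) >= 2, "need at least 2 groups")
  if (all(y == 0)) stop("degenerate response: all counts are zero", call. = FALSE)
  assert_that(qr(X)$rank == p, "design matrix is not full rank")

  ord <- order(group)
  y_o <- as.numeric(y[ord]); X_o <- X[ord, , drop = FALSE]
  g_o <- group[ord]
  gsize <- as.integer(table(g_o)[unique(g_o)])
  gstart <- as.integer(cumsum(c(0L, gsize[-length(gsize)])))
  rule <- gh_rule(nAGQ)

  start_glm <- fit_nb_glm_core(y, X, theta_bounds, tol = 1e-3, max_iter = 20,
                               profile_tol = 1e-4)
  start <- c(start_glm$coefficients, log(start_glm$theta), 0.5)
  lower <- c(rep(-Inf, p), log(theta_bounds[1]), -20)
  upper <- c(rep(Inf, p), log(theta_bounds[2]), 20)

  bcache <- numeric(length(gsize))
  obj <- function(par) nb_glmm_nll_cpp(par, y_o, X_o, gstart, gsize,
                                       rule$z, rule$w, bcache)
  opt <- stats::nlminb(start, obj, lower = lower, upper = upper,
                       control = list(iter.max = max_iter,
                                      eval.max = 4 * max_iter,
                                      rel.tol = tol * 1e-2))
  if (opt$convergence != 0) {   # polish with a derivative-free pass
    opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-10))
    if (opt2$value <= opt$objective)
      opt <- list(par = opt2$par, objective = opt2$value,
                  convergence = if (opt2$convergence == 0) 0L else 1L)
  }

  par <- opt$par
  beta <- setNames(par[1:p], colnames(X))
  theta <- unname(exp(par[p + 1])); sigma <- unname(abs(par[p + 2]))
  singleton_groups <- all(gsize == 1)
  boundary <- sigma < 1e-3 || singleton_groups
  sigma_b <- if (sigma < 1e-3) 0 else sigma

  H <- numeric_hessian(obj, par)
  vc_all <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc_all) || any(!is.finite(diag(vc_all)[1:p])) ||
      any(diag(vc_all)[1:p] <= 0)) {
    # variance components at the boundary flatten the full Hessian;
    # condition on them and invert the beta block alone
    Hb <- H[1:p, 1:p, drop = FALSE]
    vc <- tryCatch(solve(Hb), error = function(e) matrix(NA_real_, p, p))
  } else {
    vc <- vc_all[1:p, 1:p, drop = FALSE]
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(vc), 0))

  eta <- pmin(pmax(drop(X %*% beta), -40), 40)
  list(coefficients = beta, se = se, vcov = vc, theta = theta,
       sigma_b = sigma_b, logLik = -opt$objective,
       converged = opt$convergence == 0 && all(is.finite(se)),
       boundary = boundary, iterations = opt$iterations %||% NA_integer_,
       fitted = exp(eta), y = y, X = X, group = group, nAGQ = nAGQ)
}

#' @noRd
numeric_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(x))
  f0 <- f(x)
  H <- matrix(0, k, k)
  fp <- fm <- numeric(k)
  for (j in 1:k) {
    xp <- x; xp[j] <- xp[j] + h[j]
    xm <- x; xm[j] <- xm[j] - h[j]
    fp[j] <- f(xp); fm[j] <- f(xm)
    H[j, j] <- (fp[j] + fm[j] - 2 * f0) / h[j]^2
  }
  if (k > 1) {
    for (j in 1:(k - 1)) for (l in (j + 1):k) {
      xpp <- x; xpp[j] <- xpp[j] + h[j]; xpp[l] <- xpp[l] + h[l]
      xmm <- x; xmm[j] <- xmm[j] - h[j]; xmm[l] <- xmm[l] - h[l]
      H[j, l] <- H[l, j] <-
        (f(xpp) + f(xmm) - fp[j] - fm[j] - fp[l] - fm[l] + 2 * f0) /
        (2 * h[j] * h[l])
    }
  }
  H
}

# -- methods -----------------------------------------------------------------

#' @export
print.nb_fit <- function(x, digits = 4, ...) {
  cat("Negative binomial", if (!is.null(x$group)) "mixed model" else "GLM",
      "(log link)\n")
  cat("Call: ", paste(deparse(x$call), collapse = ""), "\n\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\ntheta = %.4g", x$theta))
  if (!is.null(x$group)) cat(sprintf(", sigma_b = %.4g", x$sigma_b))
  cat(sprintf(", logLik = %.4f%s\n", x$logLik,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' @export
summary.nb_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(call = object$call, coefficients = tab,
                 theta = object$theta, sigma_b = object$sigma_b,
                 logLik = object$logLik, converged = object$converged,
                 boundary = object$boundary, mixed = !is.null(object$group)),
            class = "summary.nb_fit")
}

#' @export
print.summary.nb_fit <- function(x, digits = 4, ...) {
  cat("Negative binomial", if (x$mixed) "mixed model" else "GLM", "(log link)\n")
  cat("Call: ", paste(deparse(x$call), collapse = ""), "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\ntheta = %.4g", x$theta))
  if (x$mixed) cat(sprintf(", sigma_b = %.4g", x$sigma_b))
  cat(sprintf(", logLik = %.4f%s%s\n", x$logLik,
              if (x$boundary) " (boundary)" else "",
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' @export
coef.nb_fit <- function(object, ...) object$coefficients

#' @export
vcov.nb_fit <- function(object, ...) object$vcov

#' @export
logLik.nb_fit <- function(object, ...) {
  p <- length(object$coefficients) + 1 + as.integer(!is.null(object$group))
  structure(object$logLik, df = p, nobs = length(object$y), class = "logLik")
}

#' @export
fitted.nb_fit <- function(object, ...) object$fitted

#' @export
predict.nb_fit <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- log(object$fitted)
  } else {
    X <- stats::model.matrix(object$fixed_terms, newdata)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") exp(eta) else eta
}

#' @export
residuals.nb_fit <- function(object,
                             type = c("pearson", "deviance", "response"),
                             ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted; th <- object$theta
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu + mu^2 / th),
    deviance = {
      term <- ifelse(y > 0, y * log(y / mu), 0) -
        (y + th) * log((y + th) / (mu + th))
      sign(y - mu) * sqrt(pmax(2 * term, 0))
    })
}

#' @export
simulate.nb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$y)
  out <- as.data.frame(matrix(NA_real_, n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  for (s in seq_len(nsim)) {
    mu <- object$fitted
    if (!is.null(object$group) && object$sigma_b > 0) {
      g <- unique(object$group)
      b <- setNames(rnorm(length(g), 0, object$sigma_b), g)
      mu <- mu * exp(b[object$group])
    }
    out[[s]] <- rnbinom(n, mu = mu, size = object$theta)
  }
  out
}
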