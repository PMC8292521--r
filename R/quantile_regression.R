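# Median (quantile) regression via a primal-dual interior-point solver.
#
# The tau-th regression quantile minimises the check-function loss
#   sum_i rho_tau(y_i - x_i' b),  rho_tau(u) = u (tau - 1{u < 0}),
# which for tau = 0.5 is least-absolute-deviations regression. The dual is
# the box-constrained LP  max y'd  s.t.  X'd = (1 - tau) X'1, d in [0,1]^n,
# solved here with a Frisch-Newton primal-dual interior-point iteration
# with Mehrotra predictor-corrector steps; the regression coefficients are
# the (negated) equality multipliers. Because an interior-point iterate can
# stop in the interior of an optimal face when the solution is non-unique,
# the estimate is polished to a vertex: a basic solution interpolating p
# observations with the smallest absolute residuals, accepted only if it
# does not increase the objective.

# max step in [0, 1e20] keeping v + f*dv > 0
.bound_step <- function(v, dv) {
  i <- dv < 0
  if (!any(i)) return(1e20)
  min(-v[i] / dv[i])
}

# Solve min c'x s.t. A x = b, 0 <= x <= u (A is p x n) by interior point.
# Returns the dual vector of the equality constraints.
.lp_fnm <- function(A, c, b, u, x, tol = 1e-10, max_it = 200) {
  beta_step <- 0.9995
  p <- nrow(A); n <- ncol(A)
  s <- u - x
  y <- qr.solve(t(A), c)
  r <- c - as.numeric(crossprod(A, y))
  r <- r + 1e-3 * (abs(r) < 1e-15)
  z <- pmax(r, 0)
  w <- z - r
  gap <- sum(c * x) - sum(y * b) + sum(u * w)
  it <- 0
  solve_sys <- function(AQ, Achol, rhs) {
    if (!is.null(Achol))
      return(backsolve(Achol, backsolve(Achol, rhs, transpose = TRUE)))
    # near-degenerate normal matrix (can happen close to convergence):
    # ridge-regularise just enough to keep the step well-defined
    ridge <- 1e-12 * max(diag(AQ))
    for (k in 1:6) {
      out <- tryCatch(solve(AQ + diag(ridge, nrow(AQ)), rhs),
                      error = function(e) NULL)
      if (!is.null(out)) return(out)
      ridge <- ridge * 100
    }
    stop("interior-point normal equations are numerically singular")
  }
  while (gap > tol && it < max_it) {
    it <- it + 1
    q <- 1 / (z / x + w / s)
    rr <- z - w
    Aq <- A * rep(q, each = p)          # A %*% diag(q)
    AQA <- tcrossprod(Aq, A)
    Achol <- tryCatch(chol(AQA), error = function(e) NULL)
    rhs <- as.numeric(A %*% (q * rr))
    dy <- solve_sys(AQA, Achol, rhs)
    dx <- q * (as.numeric(crossprod(A, dy)) - rr)
    ds <- -dx
    dz <- -z * (1 + dx / x)
    dw <- -w * (1 + ds / s)
    fp <- min(beta_step * min(.bound_step(x, dx), .bound_step(s, ds)), 1)
    fd <- min(beta_step * min(.bound_step(z, dz), .bound_step(w, dw)), 1)
    if (min(fp, fd) < 1) {                      # Mehrotra corrector
      mu <- sum(z * x) + sum(w * s)
      g <- sum((z + fd * dz) * (x + fp * dx)) +
           sum((w + fd * dw) * (s + fp * ds))
      mu <- mu * (g / mu)^3 / (2 * n)
      dxdz <- dx * dz; dsdw <- ds * dw
      xinv <- 1 / x; sinv <- 1 / s
      xi <- mu * (xinv - sinv)
      rhs <- rhs + as.numeric(A %*% (q * (dxdz - dsdw - xi)))
      dy <- solve_sys(AQA, Achol, rhs)
      dx <- q * (as.numeric(crossprod(A, dy)) + xi - rr - (dxdz - dsdw))
      ds <- -dx
      dz <- mu * xinv - z - xinv * z * dx - dxdz
      dw <- mu * sinv - w - sinv * w * ds - dsdw
      fp <- min(beta_step * min(.bound_step(x, dx), .bound_step(s, ds)), 1)
      fd <- min(beta_step * min(.bound_step(z, dz), .bound_step(w, dw)), 1)
    }
    x <- x + fp * dx; s <- s + fp * ds
    y <- y + fd * dy; z <- z + fd * dz; w <- w + fd * dw
    gap <- sum(c * x) - sum(y * b) + sum(u * w)
  }
  y
}

# check-function loss
.rho_tau <- function(res, tau) sum(res * (tau - (res < 0)))

# polish an interior-point estimate to a basic (vertex) solution that
# interpolates p linearly independent observations with smallest |residual|
.polish_vertex <- function(X, y, beta, tau) {
  n <- nrow(X); p <- ncol(X)
  res <- y - as.numeric(X %*% beta)
  obj0 <- .rho_tau(res, tau)
  ord <- order(abs(res), seq_len(n))
  idx <- integer(0)
  for (i in ord) {
    cand <- c(idx, i)
    if (qr(X[cand, , drop = FALSE])$rank == length(cand)) idx <- cand
    if (length(idx) == p) break
  }
  if (length(idx) < p) return(beta)
  bv <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                 error = function(e) NULL)
  if (is.null(bv)) return(beta)
  if (.rho_tau(y - as.numeric(X %*% bv), tau) <= obj0 + 1e-9 * (1 + abs(obj0)))
    bv else beta
}

# core solver: design matrix in, coefficient vector out
.rq_solve <- function(X, y, tau = 0.5, polish = TRUE) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dep <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  a <- rep(1 - tau, n)
  dual <- .lp_fnm(t(X), -y, as.numeric(crossprod(X, a)), rep(1, n), a)
  beta <- -dual
  names(beta) <- colnames(X)
  if (polish) beta <- setNames(.polish_vertex(X, y, beta, tau), colnames(X))
  beta
}

#' Median (quantile) regression with bootstrap inference
#'
#' Fits the conditional median (or another quantile \code{tau}) of the
#' outcome on the design by minimising the check-function loss, solved as
#' a linear program with a Frisch-Newton interior-point iteration and
#' vertex polishing. 95\% confidence intervals and P values are obtained
#' by a nonparametric bootstrap (resampling observations with replacement;
#' percentile intervals; normal-approximation P values from the bootstrap
#' SE), reproducible given \code{seed}. Median regression is robust to
#' non-normality of the outcome, which is why it is the convention for
#' skewed uptake fractions.
#'
#' @param formula Model formula, e.g. \code{fraction ~ age + weight + sex}.
#' @param data \code{data.frame} holding the variables.
#' @param tau Quantile level (default 0.5, the median).
#' @param n_boot Number of bootstrap resamples (0 disables inference).
#' @param conf_level Confidence level for percentile intervals.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class \code{"median_fit"}: \code{coefficients},
#'   \code{objective} (check loss at the solution), \code{ci} (matrix),
#'   \code{p_value}, \code{boot} (B x p coefficient matrix), \code{fitted},
#'   \code{residuals}, \code{tau}, \code{n}.
#' @examples
#' d <- data.frame(x = c(0, 0, 0, 1, 1, 1, 1),
#'                 y = c(0.29, 0.30, 0.31, 0.36, 0.37, 0.36, 0.35))
#' coef(median_regression(y ~ x, d, n_boot = 0))
#' @export
median_regression <- function(formula, data, tau = 0.5, n_boot = 2000,
                              conf_level = 0.95, seed = 1) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  beta <- .rq_solve(X, y, tau)
  res <- y - as.numeric(X %*% beta)
  out <- list(coefficients = beta, objective = .rho_tau(res, tau),
              fitted = as.numeric(X %*% beta), residuals = res,
              tau = tau, n = nrow(X), formula = formula,
              ci = NULL, p_value = NULL, boot = NULL)
  if (n_boot > 0) {
    bmat <- with_seed(seed, {
      m <- matrix(NA_real_, n_boot, ncol(X), dimnames = list(NULL, colnames(X)))
      for (b in seq_len(n_boot)) {
        i <- sample.int(nrow(X), replace = TRUE)
        cf <- tryCatch(.rq_solve(X[i, , drop = FALSE], y[i], tau),
                       error = function(e) rep(NA_real_, ncol(X)))
        m[b, ] <- cf
      }
      m
    })
    alpha <- 1 - conf_level
    ci <- t(apply(bmat, 2, quantile,
                  probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
    colnames(ci) <- c("lower", "upper")
    se <- apply(bmat, 2, sd, na.rm = TRUE)
    pv <- ifelse(se > 0, 2 * pnorm(-abs(beta / se)),
                 as.numeric(beta != 0) * 0)
    out$ci <- ci
    out$p_value <- pv
    out$boot <- bmat
  }
  class(out) <- "median_fit"
  out
}

#' @method print median_fit
#' @export
print.median_fit <- function(x, ...) {
  cat(sprintf("Quantile regression (tau = %g), n = %d\n", x$tau, x$n))
  tab <- data.frame(coefficient = x$coefficients)
  if (!is.null(x$ci)) {
    tab$ci_low <- x$ci[, 1]; tab$ci_high <- x$ci[, 2]
    tab$p_value <- x$p_value
  }
  print(round(tab, 4))
  invisible(x)
}

#' @method coef median_fit
#' @export
coef.median_fit <- function(object, ...) object$coefficients

# age categories used in the covariate analysis (reference 0 to <3 years)
.age_category <- function(age) {
  cut(age, breaks = c(0, 3, 7, 13, Inf), right = FALSE,
      labels = c("0 to <3 years", "3 to <7 years",
                 "7 to <13 years", ">=13 years"),
      include.lowest = TRUE)
}

#' Univariate and multivariable covariate analysis of kidney uptake
#'
#' Runs the median-regression covariate analysis of the kidney activity
#' fraction at the clinical imaging time: univariate regressions on age
#' (per year), age category (reference 0 to <3 years), weight (per 5 kg)
#' and sex (female vs male reference), and a multivariable regression on
#' age + weight + sex. One row per patient is used - the SPECT measurement
#' at the clinical time point. Empty age-category levels are dropped with
#' a warning.
#'
#' @param records \code{data.frame} of uptake records with columns
#'   \code{patient_id}, \code{age_y}, \code{weight_kg}, \code{sex}
#'   (\code{"male"}/\code{"female"}), \code{modality}, \code{fraction}.
#'   Rows with \code{modality == "SPECT"} are used (one per patient).
#' @param n_boot Bootstrap resamples for CIs/P values.
#' @param seed RNG seed.
#' @param alpha Significance threshold (default 0.05).
#' @return List with elements \code{univariate} and \code{multivariable},
#'   each a \code{data.frame} with columns \code{term},
#'   \code{coefficient}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{significant}.
#' @export
run_covariate_regression <- function(records, n_boot = 2000, seed = 1,
                                     alpha = 0.05) {
  d <- records[records$modality == "SPECT", , drop = FALSE]
  if (anyDuplicated(d$patient_id))
    stop("expected one clinical-time SPECT record per patient")
  d <- data.frame(fraction = d$fraction, age = d$age_y,
                  weight5 = d$weight_kg / 5,
                  female = as.numeric(d$sex == "female"),
                  age_cat = .age_category(d$age_y))
  present <- levels(d$age_cat)[table(d$age_cat) > 0]
  if (length(present) < nlevels(d$age_cat)) {
    warning("dropping empty age-category level(s): ",
            paste(setdiff(levels(d$age_cat), present), collapse = ", "))
    d$age_cat <- droplevels(d$age_cat)
  }
  grab <- function(fit, terms, labels) {
    data.frame(term = labels,
               coefficient = fit$coefficients[terms],
               ci_low = fit$ci[terms, 1],
               ci_high = fit$ci[terms, 2],
               p_value = fit$p_value[terms],
               row.names = NULL)
  }
  u1 <- median_regression(fraction ~ age, d, n_boot = n_boot, seed = seed)
  u2 <- median_regression(fraction ~ age_cat, d, n_boot = n_boot, seed = seed + 1)
  u3 <- median_regression(fraction ~ weight5, d, n_boot = n_boot, seed = seed + 2)
  u4 <- median_regression(fraction ~ female, d, n_boot = n_boot, seed = seed + 3)
  cat_terms <- grep("^age_cat", names(u2$coefficients), value = TRUE)
  uni <- rbind(
    grab(u1, "age", "Age (per year)"),
    grab(u2, cat_terms, sub("^age_cat", "Age category ", cat_terms)),
    grab(u3, "weight5", "Weight (per 5 kg)"),
    grab(u4, "female", "Female"))
  m <- median_regression(fraction ~ age + weight5 + female, d,
                         n_boot = n_boot, seed = seed + 4)
  multi <- grab(m, c("age", "weight5", "female"),
                c("Age (per year)", "Weight (per 5 kg)", "Female"))
  uni$significant <- uni$p_value < alpha
  multi$significant <- multi$p_value < alpha
  list(univariate = uni, multivariable = multi)
}
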