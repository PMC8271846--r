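# Generalized estimating equations for the longitudinal method comparison:
# Gaussian outcome, identity link, exchangeable working correlation, robust
# (sandwich) covariance. Factors: time (weeks 3/12/26, reference week 3),
# method (sit/stand reference, so the method coefficient is the whole-body-
# movement effect), and their interaction. Implemented here from the
# estimating equations; moment estimators for the scale and the exchangeable
# correlation follow the usual GEE1 conventions.

# Core solver. X: n x p design; y: response; id: cluster factor.
# Iterates beta -> (phi, rho) -> beta until the coefficients stabilise.
gee_exchangeable <- function(X, y, id, tol = 1e-10, maxit = 100) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  cl <- split(seq_len(n), id)
  if (length(cl) < 2) {
    stop("GEE needs at least 2 clusters (subjects); got ", length(cl), call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank-deficient", call. = FALSE)
  beta <- qr.coef(qrX, y)
  rho <- 0; phi <- stats::var(y)
  max_ni <- max(lengths(cl))

  for (it in seq_len(maxit)) {
    r <- as.vector(y - X %*% beta)
    phi <- sum(r^2) / (n - p)
    num <- 0; den <- 0
    for (idx in cl) {
      ni <- length(idx)
      if (ni >= 2) {
        ri <- r[idx]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    rho <- if (den > p) (num / phi) / (den - p) else 0
    rho <- min(max(rho, -1 / max(max_ni - 1, 1) + 1e-6), 1 - 1e-6)

    A <- matrix(0, p, p); b <- numeric(p)
    for (idx in cl) {
      ni <- length(idx)
      Xi <- X[idx, , drop = FALSE]
      yi <- y[idx]
      # V^-1 = (1/phi) * (1/(1-rho)) * (I - rho/(1+(ni-1)rho) * J)
      c1 <- 1 / (phi * (1 - rho))
      c2 <- rho / (1 + (ni - 1) * rho)
      XtVi <- c1 * (t(Xi) - c2 * outer(colSums(Xi), rep(1, ni)))
      A <- A + XtVi %*% Xi
      b <- b + XtVi %*% yi
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (delta < tol) break
  }

  # sandwich covariance
  r <- as.vector(y - X %*% beta)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (idx in cl) {
    ni <- length(idx)
    Xi <- X[idx, , drop = FALSE]
    c1 <- 1 / (phi * (1 - rho))
    c2 <- rho / (1 + (ni - 1) * rho)
    XtVi <- c1 * (t(Xi) - c2 * outer(colSums(Xi), rep(1, ni)))
    B <- B + XtVi %*% Xi
    ui <- XtVi %*% r[idx]
    M <- M + ui %*% t(ui)
  }
  Binv <- solve(B)
  vcov_robust <- Binv %*% M %*% Binv
  beta <- unname(beta)
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = vcov_robust, vcov_naive = Binv,
       rho = rho, phi = phi, n_clusters = length(cl), n_obs = n,
       iterations = it, converged = delta < tol)
}

#' Fit the longitudinal GEE model for one arm-use outcome
#'
#' Fits `value ~ time * method` by Gaussian GEE with an exchangeable working
#' correlation, clustering on subject. Time is categorical with week 3 as
#' reference; the method reference is the sit/stand method, so the `method`
#' coefficient estimates the whole-body-movement effect at week 3. Missing
#' subject-weeks are permitted (clusters may be unbalanced).
#'
#' @param data long-format data frame with columns `subject_id`, `week`,
#'   `method` (`"sitstand"`/`"pm"`), and `value`.
#' @param weeks factor levels for the time factor.
#' @return Object of class `arm_gee`: coefficient table with robust standard
#'   errors and Wald p-values, multi-df Wald tests per factor, and the
#'   working-correlation estimate.
#' @seealso [posthoc_contrasts()] for Bonferroni-adjusted pairwise contrasts.
#' @export
fit_gee <- function(data, weeks = c(3, 12, 26)) {
  need <- c("subject_id", "week", "method", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  data <- data[stats::complete.cases(data[need]), , drop = FALSE]
  data$time <- factor(data$week, levels = intersect(weeks, unique(data$week)))
  data$method <- factor(data$method, levels = c("sitstand", "pm"))
  obs_per_cluster <- table(data$subject_id)
  if (sum(obs_per_cluster >= 2) < 2) {
    stop("GEE is not estimable: need >= 2 subjects with >= 2 observations each",
         call. = FALSE)
  }
  mf <- stats::model.frame(value ~ time * method, data = data)
  X <- stats::model.matrix(value ~ time * method, mf)
  fit <- gee_exchangeable(X, mf$value, data$subject_id)

  se <- sqrt(pmax(diag(fit$vcov), 0))
  z <- fit$coefficients / se
  coef_table <- tibble::tibble(
    term = colnames(X), estimate = unname(fit$coefficients),
    robust_se = se, z = z, p = 2 * stats::pnorm(-abs(z)))

  # multi-df Wald tests per factor on the robust covariance
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(value ~ time * method), "term.labels")
  wald <- lapply(seq_along(labels), function(a) {
    k <- which(assign == a)
    w <- tryCatch(
      as.numeric(t(fit$coefficients[k]) %*%
                   solve(fit$vcov[k, k, drop = FALSE], fit$coefficients[k])),
      error = function(e) NA_real_)
    tibble::tibble(factor = labels[a], df = length(k), wald_chisq = w,
                   p = stats::pchisq(w, length(k), lower.tail = FALSE))
  })

  structure(list(coefficients = coef_table, wald = dplyr::bind_rows(wald),
                 vcov = fit$vcov, rho = fit$rho, phi = fit$phi,
                 n_clusters = fit$n_clusters, n_obs = fit$n_obs,
                 converged = fit$converged, design_terms = colnames(X),
                 weeks = levels(data$time)),
            class = "arm_gee")
}

#' @export
print.arm_gee <- function(x, ...) {
  cat(sprintf(
    "Gaussian GEE, exchangeable working correlation (rho = %.3f, phi = %.3g)\n",
    x$rho, x$phi))
  cat(sprintf("%d observations in %d clusters\n\n", x$n_obs, x$n_clusters))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  cat("\nWald tests (robust covariance):\n")
  print(as.data.frame(x$wald), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-adjusted post-hoc contrasts for the GEE fit
#'
#' Contrast family: the method contrast (P&M minus sit/stand) within each
#' week, and the pairwise between-week contrasts within each method — with
#' three weeks, m = 3 + 6 = 9 contrasts. The family size used is reported,
#' and adjusted p-values are `min(1, m * p)`.
#'
#' @param fit an `arm_gee` object.
#' @return Tibble of contrasts with estimates, robust SEs, raw and
#'   Bonferroni-adjusted p-values; the family size is in attribute `"m"` and
#'   column `m`.
#' @export
posthoc_contrasts <- function(fit) {
  terms <- fit$design_terms
  p <- length(terms)
  beta <- fit$coefficients$estimate
  wks <- fit$weeks
  Lrow <- function(active) {
    L <- numeric(p)
    L[match(active, terms)] <- 1
    L
  }
  tm <- function(w) paste0("time", w)
  int <- function(w) paste0("time", w, ":methodpm")

  rows <- list()
  # method effect within each week
  for (w in wks) {
    active <- "methodpm"
    if (w != wks[1]) active <- c(active, int(w))
    rows[[length(rows) + 1L]] <- list(
      contrast = sprintf("pm - sitstand | week %s", w), L = Lrow(active))
  }
  # between-week contrasts within each method
  if (length(wks) >= 2) {
    pairs <- utils::combn(wks, 2, simplify = FALSE)
    for (m_lab in c("sitstand", "pm")) {
      for (pr in pairs) {
        a1 <- if (pr[2] != wks[1]) tm(pr[2]) else character(0)
        a0 <- if (pr[1] != wks[1]) tm(pr[1]) else character(0)
        if (m_lab == "pm") {
          a1 <- c(a1, if (pr[2] != wks[1]) int(pr[2]) else character(0))
          a0 <- c(a0, if (pr[1] != wks[1]) int(pr[1]) else character(0))
        }
        L <- Lrow(a1) - Lrow(a0)
        rows[[length(rows) + 1L]] <- list(
          contrast = sprintf("week %s - week %s | %s", pr[2], pr[1], m_lab),
          L = L)
      }
    }
  }
  m <- length(rows)
  out <- lapply(rows, function(rw) {
    est <- sum(rw$L * beta)
    se <- sqrt(as.numeric(t(rw$L) %*% fit$vcov %*% rw$L))
    z <- est / se
    praw <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(contrast = rw$contrast, estimate = est, robust_se = se,
                   z = z, p = praw, p_bonferroni = min(1, m * praw), m = m)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "m") <- m
  res
}

#' Reshape weekly outcomes to the long method format for the GEE
#'
#' @param weekly weekly outcome tibble (see [aggregate_weekly()]).
#' @param outcome one of `"paretic"`, `"nonparetic"`, `"ratio"`.
#' @return Long tibble with columns `subject_id, week, method, value`.
#' @export
weekly_to_long <- function(weekly, outcome = "paretic") {
  outcome <- match.arg(outcome, OUTCOMES)
  tidyr::pivot_longer(
    weekly[, c("subject_id", "week", paste0(outcome, c("_pm", "_ss")))],
    cols = dplyr::all_of(paste0(outcome, c("_pm", "_ss"))),
    names_to = "method", values_to = "value") |>
    dplyr::mutate(method = ifelse(endsWith(method, "_pm"), "pm", "sitstand"))
}
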