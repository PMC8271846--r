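# Shared fixtures and independent oracles for the test suite. Cohorts are
# generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The packaged demonstration cohort: 12 subjects, weeks 3/12/26, 3 days each,
# default effect structure (sway on, walking increasing over weeks).
demo_cohort <- function() {
  cached("demo_cohort", simulate_cohort(fixture_config(seed = 42)))
}

demo_weekly <- function() {
  cached("demo_weekly", process_cohort(demo_cohort()$recordings)$weekly)
}

# Tiny clean cohort (no non-wear, no missingness) for exact-recovery checks.
clean_cohort <- function(n_subjects = 3, weeks = c(3), days = 2, seed = 11, ...) {
  key <- paste("clean", n_subjects, paste(weeks, collapse = "-"), days, seed)
  cached(key, simulate_cohort(disable_dropout(
    sim_config(n_subjects = n_subjects, weeks = weeks, days_per_week = days,
               seed = seed, ...))))
}

# Build a one-day, three-stream recording from per-epoch specifications.
# counts: list(paretic=, nonparetic=, thigh=) each a length-n vector of
# per-epoch constant sample counts, or an n x 48 matrix. labels: vector of
# per-epoch labels (recycled across the 48 samples) or an n x 48 matrix.
make_recording <- function(labels, paretic = 0, nonparetic = 0, thigh = 0,
                           date = as.Date("2023-05-01"), start_clock = "07:00",
                           subject_id = "T01", week = 3) {
  as_mat <- function(x, n) {
    if (is.matrix(x)) return(x)
    matrix(rep(x, each = 48), nrow = n, ncol = 48, byrow = TRUE)
  }
  lab_mat <- if (is.matrix(labels)) labels else
    matrix(rep(labels, times = 48), nrow = length(labels), ncol = 48)
  n <- nrow(lab_mat)
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + parse_clock_test(start_clock)
  st <- t0 + (seq_len(n) - 1) * 30
  arm_recording(list(
    paretic_wrist = epoch_stream(subject_id, week, "paretic_wrist", st,
                                 as_mat(paretic, n)),
    nonparetic_wrist = epoch_stream(subject_id, week, "nonparetic_wrist", st,
                                    as_mat(nonparetic, n)),
    thigh = epoch_stream(subject_id, week, "thigh", st, as_mat(thigh, n),
                         labels = lab_mat)))
}

parse_clock_test <- function(x) {
  p <- as.numeric(strsplit(x, ":")[[1]])
  p[1] * 3600 + p[2] * 60
}

# A full valid day: n_epochs of sitting with nonzero counts everywhere.
full_sit_day <- function(n_epochs = 1800, ...) {
  make_recording(labels = rep("SIT", n_epochs), paretic = 1, nonparetic = 1,
                 thigh = 1, ...)
}

# Independent GEE oracle: an iteratively-reweighted estimating-equation
# solver written from scratch against the same moment conventions, but by a
# different numerical route — it materialises the full block-diagonal working
# covariance as a dense N x N matrix and solves the weighted normal equations
# with solve(), instead of the per-cluster Woodbury shortcut the package
# uses.
gee_direct_oracle <- function(X, y, id, tol = 1e-12, maxit = 200) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  cl <- split(seq_len(n), id)
  max_ni <- max(lengths(cl))
  beta <- qr.solve(X, y)
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
    V <- matrix(0, n, n)
    for (idx in cl) {
      ni <- length(idx)
      V[idx, idx] <- phi * (rho * matrix(1, ni, ni) + (1 - rho) * diag(ni))
    }
    Vinv <- solve(V)
    beta_new <- solve(t(X) %*% Vinv %*% X, t(X) %*% Vinv %*% y)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- as.vector(beta_new)
      break
    }
    beta <- as.vector(beta_new)
  }
  beta
}
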