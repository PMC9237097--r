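# Independent oracles used across the suite. These deliberately re-derive
# results through different algorithms / code paths than the package.

# SVD-based PLS1: the weight vector of each component is the leading left
# singular vector of the cross-product matrix X'y (computed via svd()),
# with explicit X and y deflation. Independent of the package's NIPALS
# power-style extraction.
pls_svd_oracle <- function(X, y, A) {
  X <- as.matrix(X)
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
  Xd <- scale(X, mx, sx)
  my <- mean(y); yr <- y - my
  p <- ncol(Xd)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  for (a in seq_len(A)) {
    s <- svd(crossprod(Xd, matrix(yr)))
    w <- s$u[, 1] * sign(sum(s$u[, 1] * crossprod(Xd, yr)))  # orient like X'y
    tt <- Xd %*% w
    tt2 <- drop(crossprod(tt))
    if (tt2 < 1e-12) { A <- a - 1L; break }
    pp <- drop(crossprod(Xd, tt)) / tt2
    qq <- drop(crossprod(yr, tt)) / tt2
    Xd <- Xd - tt %*% t(pp)
    yr <- yr - qq * drop(tt)
    W[, a] <- w; P[, a] <- pp; q[a] <- qq
  }
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]
  B <- W %*% solve(crossprod(P, W), q)
  list(predict = function(newX, ncomp = A) {
    Wa <- W[, seq_len(ncomp), drop = FALSE]
    Pa <- P[, seq_len(ncomp), drop = FALSE]
    Ba <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(ncomp)])
    drop(scale(as.matrix(newX), mx, sx) %*% Ba) + my
  })
}

# Transient radon box model integrated to equilibrium with deSolve:
# V dC/dt = F_gw + f_diff*A + Q_in*C_in + lam*V*C_Ra
#           - k*A*(C - C_eq) - Q_out*C - lam*V*C
ode_equilibrium_conc <- function(par, t_end = NULL) {
  lam <- log(2) / 3.82
  rhs <- function(t, state, p) {
    C <- state[1]
    dC <- (p$f_gw + p$f_diff * p$A + p$q_in * p$c_in + lam * p$V * p$c_ra -
             p$k * p$A * (C - p$c_eq) - p$q_out * C - lam * p$V * C) / p$V
    list(dC)
  }
  tau <- 1 / (lam + par$q_out / par$V + par$k / (par$V / par$A))
  t_end <- t_end %||% (30 * tau)
  out <- deSolve::ode(y = c(C = 0), times = c(0, t_end), func = rhs,
                      parms = par, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  unname(out[nrow(out), "C"])
}

# Build an exact (noise-free) lake_survey around a known lake concentration,
# for forward/inverse identity checks.
survey_from_params <- function(par, c_lake) {
  samples <- tibble::tibble(
    lake_id = "ORACLE", season = "summer",
    source = c("lake_surface", "inlet", "outlet", "groundwater"),
    rn_bq_m3 = c(c_lake, par$c_in, c_lake, 5000),
    ch4_umol_l = c(0.2, 0.02, 0.2, 150),
    temp_c = 12
  )
  wind <- tibble::tibble(timestamp = 1:48, speed_m_s = 4, height_m = 10)
  suppressMessages(lakegw::lake_survey(
    geometry = lakegw::lake_geometry("ORACLE", par$A, par$V, par$V / par$A),
    samples = samples, wind = wind,
    flows = list(q_inlet = lakegw::uv(par$q_in, 0),
                 q_outlet = lakegw::uv(par$q_out, 0)),
    f_diff = lakegw::uv(par$f_diff, 0),
    c_ra_lake = lakegw::uv(par$c_ra, 0),
    season = "summer"
  ))
}

# Random positive budget parameter set (scales loosely span small lakes)
random_budget_params <- function() {
  A <- runif(1, 1e4, 2e5)
  list(
    A = A, V = A * runif(1, 1, 6),
    k = runif(1, 0.2, 2), f_diff = runif(1, 0, 50),
    q_in = runif(1, 0, 2e4), c_in = runif(1, 0, 2000),
    q_out = runif(1, 0, 3e4), c_ra = runif(1, 0, 100),
    c_eq = 0, f_gw = runif(1, 1e5, 2e7)
  )
}

# random regression problem shared by the PLS checks
random_problem <- function(seed, n = 15, p = 7) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- rnorm(p) * rbinom(p, 1, 0.6)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.5)
  list(X = tibble::as_tibble(X), y = y)
}

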