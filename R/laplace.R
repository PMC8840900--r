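# Laplace-approximated marginal likelihood for the spatial Gompertz model.
#
# Latent structure.  The linear predictor is
#   log d(s,t) = beta(t) + omega(s) + eps(s,t) + gamma' x(s,t)
# with omega ~ MVN(0, sigma_omega2 * R) over knots and eps following an
# AR(1)-in-time process with innovation covariance sigma_eps2 * R.  The
# observation likelihood depends on the fields only through
#   eta(s,t) = omega(s) + eps(s,t),
# and because omega and eps are jointly Gaussian and share the spatial
# correlation R, the stacked eta has the Kronecker prior
#   vec(eta) ~ MVN(0, C (x) R),   C[t,t'] = sigma_omega2 + Cov_eps[t,t'],
# where Cov_eps is the (stationary or unit-start) AR(1) covariance.  The
# Laplace approximation over (omega, eps) equals exact marginalization of
# the conditionally Gaussian omega direction followed by Laplace over eta,
# so the inner problem is solved in eta: dimension n_knots * n_years, inner
# Hessian H = Q + diag(obs curvature) with Q = (C (x) R)^{-1}.
#
# The outer gradient is analytic: envelope term, plus
# 0.5 tr(H^{-1} dH/dtheta) including the implicit movement of the inner
# mode (third derivatives of the observation likelihood).  Covariance-matrix
# derivatives use the Kronecker trace identities so no n_lat^2 x p storage
# is ever needed.

# ---- temporal covariance ---------------------------------------------------

# T x T covariance of eta across years: sigma_omega2 (shared spatial field)
# plus the AR(1) covariance of eps.  init = "stationary" starts the chain in
# its stationary law sigma_eps2/(1-rho^2); init = "unit" starts at variance 1
# (the literal unit-variance first-year option).
timeCov <- function(sigma_omega2, sigma_eps2, rho, n_years,
                    init = c("stationary", "unit")) {
  init <- match.arg(init)
  v <- numeric(n_years)
  v[1L] <- if (init == "stationary") sigma_eps2 / (1 - rho^2) else 1
  if (n_years > 1L) {
    for (t in 2:n_years) v[t] <- rho^2 * v[t - 1L] + sigma_eps2
  }
  C <- matrix(0, n_years, n_years)
  for (t in seq_len(n_years)) {
    for (u in t:n_years) {
      C[t, u] <- C[u, t] <- rho^(u - t) * v[t]
    }
  }
  C + sigma_omega2
}

# ---- parameter vector layout ----------------------------------------------

# theta = (beta_1..T, gamma_*, log_sigma_m2, log_kappa, [aniso_psi, aniso_h],
#          rho_t, log_sigma_omega2, log_sigma_eps2);  rho = tanh(rho_t).
thetaLayout <- function(n_years, cov_names, aniso) {
  nm <- c(paste0("beta_", seq_len(n_years)),
          if (length(cov_names)) paste0("gamma_", cov_names),
          "log_sigma_m2", "log_kappa",
          if (aniso) c("aniso_psi", "aniso_h"),
          "rho_t", "log_sigma_omega2", "log_sigma_eps2")
  type <- c(rep("beta", n_years), rep("gamma", length(cov_names)),
            "log_v", "R", if (aniso) c("R", "R"), "C", "C", "C")
  list(names = nm, type = type, n = length(nm),
       i_beta = seq_len(n_years),
       i_gamma = if (length(cov_names)) n_years + seq_along(cov_names) else integer(0),
       i_logv = n_years + length(cov_names) + 1L,
       i_R = n_years + length(cov_names) + 1L + seq_len(1L + 2L * aniso),
       i_C = n_years + length(cov_names) + 2L + 2L * aniso + 1:3)
}

thetaCovParams <- function(theta, lay) {
  iC <- lay$i_C
  list(log_kappa = theta[[lay$i_R[1L]]],
       aniso = if (length(lay$i_R) == 3L) theta[lay$i_R[2:3]] else c(0, 0),
       rho = tanh(theta[[iC[1L]]]),
       sigma_omega2 = exp(theta[[iC[2L]]]),
       sigma_eps2 = exp(theta[[iC[3L]]]))
}

# ---- internal model-data container ----------------------------------------

# Assemble the internal structure the likelihood machinery works on.
sgmData <- function(b, knot, year_idx, X, a, mesh, n_years,
                    family = "gamma", sigma_param = "cv",
                    init = "stationary", aniso = FALSE) {
  X <- as.matrix(X)
  n_knots <- mesh$n_knots
  stopifnot(length(b) == length(knot), length(b) == length(year_idx),
            nrow(X) == length(b) || ncol(X) == 0L,
            all(knot >= 1L & knot <= n_knots),
            all(year_idx >= 1L & year_idx <= n_years))
  list(b = as.numeric(b), knot = as.integer(knot),
       year_idx = as.integer(year_idx), X = X, a = a,
       coords = mesh$knots, n_knots = n_knots, n_years = n_years,
       n_lat = n_knots * n_years,
       cell = (as.integer(year_idx) - 1L) * n_knots + as.integer(knot),
       distm = as.matrix(stats::dist(mesh$knots)),
       family = family, sigma_param = sigma_param, init = init,
       aniso = aniso)
}

# scatter per-sample values into latent cells (length n_lat)
cellSum <- function(v, cell, n_lat) {
  out <- numeric(n_lat)
  s <- rowsum(v, cell)
  out[as.integer(rownames(s))] <- s
  out
}

# ---- per-theta preparation -------------------------------------------------

sgmPrep <- function(theta, data, lay) {
  cp <- thetaCovParams(theta, lay)
  if (data$aniso && any(cp$aniso != 0)) {
    tc <- data$coords %*% t(anisotropyTransform(cp$aniso[1L], cp$aniso[2L]))
    distm <- as.matrix(stats::dist(tc))
  } else {
    distm <- data$distm
  }
  R <- maternNu1(distm, exp(cp$log_kappa))
  cholR <- tryCatch(chol(R), error = function(e) {
    stop("spatial correlation matrix is not positive-definite at kappa = ",
         signif(exp(cp$log_kappa), 4), call. = FALSE)
  })
  P <- chol2inv(cholR)
  C <- timeCov(cp$sigma_omega2, cp$sigma_eps2, cp$rho, data$n_years,
               data$init)
  cholC <- chol(C)
  Cinv <- chol2inv(cholC)
  beta <- theta[lay$i_beta]
  gamma <- theta[lay$i_gamma]
  ell_fix <- log(data$a) + beta[data$year_idx] +
    if (length(gamma)) drop(data$X %*% gamma) else 0
  list(cp = cp, distm = distm, R = R, P = P, C = C, Cinv = Cinv,
       logdetR = 2 * sum(log(diag(cholR))),
       logdetC = 2 * sum(log(diag(cholC))),
       Q = kronecker(Cinv, P),
       ell_fix = ell_fix, log_v = theta[[lay$i_logv]])
}

# ---- inner problem ---------------------------------------------------------

# Newton minimization of f(eta) = sum obs nll + 0.5 eta' Q eta.
innerNewton <- function(prep, data, eta0 = NULL, tol = 1e-8,
                        max_iter = 100L) {
  n_lat <- data$n_lat
  eta <- if (is.null(eta0)) numeric(n_lat) else eta0
  fval_of <- function(eta) {
    fam <- obsFamilyDerivs(data$b, prep$ell_fix + eta[data$cell], prep$log_v,
                           data$family, data$sigma_param)
    qeta <- drop(prep$Q %*% eta)
    list(fam = fam, qeta = qeta, f = sum(fam$nll) + 0.5 * sum(eta * qeta))
  }
  st <- fval_of(eta)
  conv <- FALSE
  cholH <- NULL
  for (it in seq_len(max_iter)) {
    g <- cellSum(st$fam$g, data$cell, n_lat) + st$qeta
    if (max(abs(g)) < tol * max(1, abs(st$f))) { conv <- TRUE }
    H <- prep$Q
    dg <- cellSum(st$fam$h, data$cell, n_lat)
    diag(H) <- diag(H) + dg
    cholH <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(cholH)) {
      # curvature correction for indefinite observation Hessians
      H2 <- H
      diag(H2) <- diag(H2) + pmax(0, -dg) + 1e-8
      cholH <- chol(H2)
    }
    if (conv) break
    step <- backsolve(cholH, forwardsolve(t(cholH), g))
    tstep <- 1
    repeat {
      stNew <- fval_of(eta - tstep * step)
      if (is.finite(stNew$f) && stNew$f <= st$f + 1e-12 * abs(st$f)) break
      tstep <- tstep / 2
      if (tstep < 1e-10) break
    }
    if (tstep < 1e-10) break
    eta <- eta - tstep * step
    st <- stNew
  }
  list(eta = eta, f = st$f, fam = st$fam, qeta = st$qeta,
       cholH = cholH, converged = conv, iterations = it)
}

# ---- Laplace objective + analytic gradient ---------------------------------

# Central finite differences of the covariance builders; used for the
# anisotropy and temporal-covariance parameters where analytic forms add
# little.  log_kappa uses the closed form -u^2 K0(u).
covMatDeriv <- function(theta, j, data, lay, step = 1e-5) {
  th1 <- theta; th1[j] <- th1[j] + step
  th2 <- theta; th2[j] <- th2[j] - step
  if (lay$type[j] == "R") {
    cp1 <- thetaCovParams(th1, lay); cp2 <- thetaCovParams(th2, lay)
    mk <- function(cp) {
      co <- data$coords
      if (data$aniso && any(cp$aniso != 0)) {
        co <- co %*% t(anisotropyTransform(cp$aniso[1L], cp$aniso[2L]))
      }
      maternNu1(as.matrix(stats::dist(co)), exp(cp$log_kappa))
    }
    (mk(cp1) - mk(cp2)) / (2 * step)
  } else {
    cp1 <- thetaCovParams(th1, lay); cp2 <- thetaCovParams(th2, lay)
    (timeCov(cp1$sigma_omega2, cp1$sigma_eps2, cp1$rho, data$n_years, data$init) -
       timeCov(cp2$sigma_omega2, cp2$sigma_eps2, cp2$rho, data$n_years, data$init)) /
      (2 * step)
  }
}

# Returns closures fn(theta), gr(theta) and state(theta) sharing a cache of
# the inner solution, warm-started across calls.
makeLaplaceObjective <- function(data, lay, inner_tol = 1e-8) {
  cache <- new.env(parent = emptyenv())
  cache$eta <- NULL
  cache$theta <- NULL

  solve_at <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta) &&
        !is.null(cache$state)) {
      return(cache$state)
    }
    prep <- sgmPrep(theta, data, lay)
    inner <- innerNewton(prep, data, eta0 = cache$eta, tol = inner_tol)
    if (!inner$converged) {
      # cold restart once before giving up
      inner <- innerNewton(prep, data, eta0 = NULL, tol = inner_tol,
                           max_iter = 200L)
    }
    val <- inner$f +
      0.5 * (data$n_knots * prep$logdetC + data$n_years * prep$logdetR) +
      sum(log(diag(inner$cholH)))
    st <- list(prep = prep, inner = inner, value = val)
    cache$eta <- inner$eta
    cache$theta <- theta
    cache$state <- st
    st
  }

  fn <- function(theta) {
    st <- try(solve_at(theta), silent = TRUE)
    if (inherits(st, "try-error") || !is.finite(st$value)) return(1e10)
    st$value
  }

  gr <- function(theta) {
    st <- solve_at(theta)
    prep <- st$prep; inner <- st$inner
    fam <- inner$fam
    n_lat <- data$n_lat; x <- data$n_knots; Tn <- data$n_years
    eta <- inner$eta
    Emat <- matrix(eta, x, Tn)
    Hinv <- chol2inv(inner$cholH)
    hd <- diag(Hinv)
    t3cell <- cellSum(fam$t3, data$cell, n_lat)

    # block reductions for the Kronecker traces, via one reshape:
    #   W_P[t,t'] = sum(HinvBlock(t,t') * P)     (P symmetric)
    #   M        = sum_{t,t'} Cinv[t',t] HinvBlock(t,t')
    tmp <- matrix(aperm(array(Hinv, c(x, Tn, x, Tn)), c(1L, 3L, 2L, 4L)),
                  x * x, Tn * Tn)
    W_P <- matrix(crossprod(tmp, as.vector(prep$P)), Tn, Tn)
    M <- matrix(tmp %*% as.vector(t(prep$Cinv)), x, x)

    p <- lay$n
    # d g_total / d theta_j for every parameter, stacked column-wise
    Bmat <- matrix(0, n_lat, p)
    grad <- numeric(p)
    trace_direct <- numeric(p)
    hscat_direct <- numeric(p)

    for (j in seq_len(p)) {
      ty <- lay$type[j]
      if (ty == "beta" || ty == "gamma") {
        w <- if (ty == "beta") {
          as.numeric(data$year_idx == match(j, lay$i_beta))
        } else {
          data$X[, match(j, lay$i_gamma)]
        }
        grad[j] <- sum(fam$g * w)
        Bmat[, j] <- cellSum(fam$h * w, data$cell, n_lat)
        hscat_direct[j] <- sum(hd * cellSum(fam$t3 * w, data$cell, n_lat))
      } else if (ty == "log_v") {
        grad[j] <- sum(fam$dnll_dlv)
        Bmat[, j] <- cellSum(fam$dg_dlv, data$cell, n_lat)
        hscat_direct[j] <- sum(hd * cellSum(fam$dh_dlv, data$cell, n_lat))
      } else if (ty == "R") {
        Rdot <- if (lay$names[j] == "log_kappa") {
          maternNu1DLogKappa(prep$distm, exp(prep$cp$log_kappa))
        } else {
          covMatDeriv(theta, j, data, lay)
        }
        Pdot <- -prep$P %*% Rdot %*% prep$P
        qdot_eta <- as.vector(Pdot %*% Emat %*% t(prep$Cinv))
        grad[j] <- 0.5 * sum(eta * qdot_eta) +
          0.5 * Tn * sum(prep$P * Rdot)
        Bmat[, j] <- qdot_eta
        trace_direct[j] <- sum(M * Pdot)
      } else { # C-parameter
        Cdot <- covMatDeriv(theta, j, data, lay)
        Adot <- -prep$Cinv %*% Cdot %*% prep$Cinv
        qdot_eta <- as.vector(prep$P %*% Emat %*% t(Adot))
        grad[j] <- 0.5 * sum(eta * qdot_eta) +
          0.5 * x * sum(prep$Cinv * Cdot)
        Bmat[, j] <- qdot_eta
        trace_direct[j] <- sum(t(Adot) * W_P)
      }
    }

    V <- -Hinv %*% Bmat                    # d eta_hat / d theta
    mode_move <- colSums((hd * t3cell) * V)
    grad + 0.5 * (trace_direct + hscat_direct + mode_move)
  }

  list(fn = fn, gr = gr, state = solve_at)
}
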