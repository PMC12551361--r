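# Random-intercept binary GLMM by adaptive Gauss-Hermite quadrature.
#
# The marginal likelihood of one person (cluster) i is
#   L_i(beta, sigma) = \int prod_t F(s_it (x_it' beta + u)) phi(u; 0, sigma^2) du
# with s = 2y - 1 and F the probit or logit inverse link.  The integral is
# approximated by Gauss-Hermite quadrature adapted per cluster: nodes are
# centered at the posterior mode of u_i with spread from the curvature there.
# Within each outer iteration the adapted grid is held fixed, so the
# objective is smooth with an exact analytic gradient; the grid is refreshed
# and the parameters re-optimized until they stabilize (fixed point = AGQ
# maximum-likelihood estimate).  Per-cluster score vectors fall out of the
# same quantities, giving the cluster-robust sandwich covariance directly.

agq_grid <- function(eta, s, cl, G, sigma, nodes_t, link) {
  # posterior mode and curvature per cluster by damped Newton (concave)
  u <- numeric(G)
  for (it in 1:12) {
    z <- s * (eta + u[cl])
    g1 <- drop(rowsum(s * link$dlogF(z), cl, reorder = FALSE)) - u / sigma^2
    g2 <- drop(rowsum(link$d2logF(z), cl, reorder = FALSE)) - 1 / sigma^2
    step <- g1 / g2
    step <- pmin(pmax(step, -4), 4)
    u_new <- u - step
    if (max(abs(u_new - u)) < 1e-9) {
      u <- u_new
      break
    }
    u <- u_new
  }
  z <- s * (eta + u[cl])
  g2 <- drop(rowsum(link$d2logF(z), cl, reorder = FALSE)) - 1 / sigma^2
  sd_i <- 1 / sqrt(-g2)
  U <- outer(sd_i * sqrt(2), nodes_t$nodes)
  U <- U + u                       # G x Q node locations per cluster
  list(mode = u, sd = sd_i, U = U)
}

# log-likelihood, gradient and per-cluster scores on a FIXED adapted grid
agq_eval <- function(theta, X, s, cl, G, grid, nodes_t, link,
                     scores = FALSE) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1L])
  eta <- drop(X %*% beta)
  Q <- length(nodes_t$nodes)
  U <- grid$U
  lw <- matrix(rep(log(nodes_t$weights) + nodes_t$nodes^2, each = G), G, Q)
  lw <- lw + log(sqrt(2) * grid$sd) +
    stats::dnorm(U, 0, sigma, log = TRUE)
  Z <- s * (eta + U[cl, , drop = FALSE])   # n x Q latent indices
  jt <- link$joint(Z)
  lw <- lw + rowsum(jt$logF, cl, reorder = FALSE)
  D <- s * jt$dlogF                        # d log F at each obs x node
  mx <- apply(lw, 1, max)
  W <- exp(lw - mx)
  sw <- rowSums(W)
  ll_i <- mx + log(sw)
  P <- W / sw                        # posterior node weights per cluster

  o <- rowSums(D * P[cl, , drop = FALSE])          # obs-level weights
  g_beta_i <- rowsum(o * X, cl, reorder = FALSE)   # G x p cluster scores
  g_sig_i <- rowSums(P * (U^2 / sigma^2 - 1))      # wrt log sigma
  gr <- c(colSums(g_beta_i), sum(g_sig_i))
  out <- list(loglik = sum(ll_i), gradient = gr)
  if (scores) out$scores <- cbind(g_beta_i, g_sig_i)
  out
}

fit_glmm_core <- function(y, X, cluster, link = "probit", nodes = 9,
                          max_outer = 40, tol = 1e-7, start = NULL,
                          compute_vcov = TRUE) {
  lk <- link_funs(link)
  ord <- order(cluster)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; cluster <- cluster[ord]
  s <- 2 * y - 1
  f <- factor(cluster, levels = unique(cluster))
  cl <- as.integer(f)
  G <- nlevels(f)
  p <- ncol(X)
  nodes_t <- gauss_hermite(nodes)

  if (is.null(start)) {
    # start from the no-RE GLM
    g0 <- stats::glm.fit(X, y, family = stats::binomial(link = link))
    theta <- c(g0$coefficients, log(0.3))
    theta[!is.finite(theta)] <- 0
  } else {
    stopifnot(length(start) == p + 1L)
    theta <- start
  }

  converged <- FALSE
  ll_prev <- -Inf
  for (outer in seq_len(max_outer)) {
    beta <- theta[seq_len(p)]
    sigma <- exp(theta[p + 1L])
    grid <- agq_grid(drop(X %*% beta), s, cl, G, sigma, nodes_t, lk)
    # cache: optim calls fn and gr at the same point back to back
    cache <- new.env(parent = emptyenv())
    ev_at <- function(th) {
      key <- paste(format(th, digits = 17), collapse = ",")
      if (!identical(cache$key, key)) {
        cache$key <- key
        cache$val <- agq_eval(th, X, s, cl, G, grid, nodes_t, lk)
      }
      cache$val
    }
    opt <- stats::optim(
      theta,
      fn = function(th) -ev_at(th)$loglik,
      gr = function(th) -ev_at(th)$gradient,
      method = "L-BFGS-B",
      lower = c(rep(-Inf, p), log(1e-6)),
      upper = c(rep(Inf, p), log(25)),
      control = list(maxit = 100, factr = if (compute_vcov) 1e7 else 1e9)
    )
    delta <- max(abs(opt$par - theta))
    theta <- opt$par
    ll_now <- -opt$value
    # fixed point: refreshing the adapted grid no longer moves the optimum
    # (thresholds track the optimizer precision of the two regimes)
    tol_par <- if (compute_vcov) tol else 1e-4
    tol_ll <- if (compute_vcov) 1e-8 else 1e-6
    if (outer > 1L && (delta < tol_par ||
                       abs(ll_now - ll_prev) < tol_ll * (1 + abs(ll_now)))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll_now
  }

  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1L])
  grid <- agq_grid(drop(X %*% beta), s, cl, G, sigma, nodes_t, lk)
  ev <- agq_eval(theta, X, s, cl, G, grid, nodes_t, lk, scores = compute_vcov)
  if (!is.finite(ev$loglik)) {
    stop("non-finite marginal likelihood; try increasing the quadrature ",
         "node count")
  }

  np <- p + 1L
  nm <- c(colnames(X), "log_sigma")
  if (compute_vcov) {
    # observed information: finite differences of the analytic gradient
    H <- matrix(0, np, np)
    for (j in seq_len(np)) {
      h <- 1e-5 * (1 + abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      H[, j] <- (agq_eval(tp, X, s, cl, G, grid, nodes_t, lk)$gradient -
                   agq_eval(tm, X, s, cl, G, grid, nodes_t, lk)$gradient) / (2 * h)
    }
    H <- (H + t(H)) / 2
    info <- -H
    vcov_model <- tryCatch(solve(info), error = function(e) {
      matrix(NA_real_, np, np)
    })
    B <- crossprod(ev$scores)
    vcov_cluster <- vcov_model %*% B %*% vcov_model
    dimnames(vcov_model) <- dimnames(vcov_cluster) <- list(nm, nm)
  } else {
    vcov_model <- vcov_cluster <- matrix(NA_real_, np, np, dimnames = list(nm, nm))
  }
  names(beta) <- colnames(X)

  list(coefficients = beta, sigma = sigma, loglik = ev$loglik,
       vcov_model = vcov_model, vcov_cluster = vcov_cluster,
       n_obs = length(y), n_clusters = G, nodes = nodes,
       converged = converged && opt$convergence == 0L)
}
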