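#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: every stochastic operation draws its own seed
# from the root seed plus a stream label, so runs are reproducible end to end
# and independent operations do not share streams.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Round half away from zero (the convention used by the printed tables;
# base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a number to a fixed number of decimals under half-away-from-zero,
# with a true minus sign handled by the caller's locale (plain hyphen here).
fmt_fixed <- function(x, digits) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}

# Gauss-Hermite nodes and weights for \int exp(-t^2) f(t) dt, via
# Golub-Welsch on the Jacobi matrix of the (physicists') Hermite polynomials.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1L, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

# Stable ratio f(z)/F(z) (inverse Mills for probit) for the link derivative.
link_funs <- function(link = c("probit", "logit")) {
  link <- match.arg(link)
  if (link == "probit") {
    list(
      F = stats::pnorm,
      logF = function(z) stats::pnorm(z, log.p = TRUE),
      # d/dz log F(z) = phi(z)/Phi(z), computed on the log scale
      dlogF = function(z) exp(stats::dnorm(z, log = TRUE) -
                                stats::pnorm(z, log.p = TRUE)),
      # second derivative of log F
      d2logF = function(z) {
        r <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
        -r * (z + r)
      },
      # logF and dlogF together, sharing the expensive tail computation
      joint = function(z) {
        lp <- stats::pnorm(z, log.p = TRUE)
        list(logF = lp, dlogF = exp(stats::dnorm(z, log = TRUE) - lp))
      }
    )
  } else {
    list(
      F = stats::plogis,
      logF = function(z) stats::plogis(z, log.p = TRUE),
      dlogF = function(z) stats::plogis(-z),
      d2logF = function(z) -stats::dlogis(z),
      joint = function(z) {
        list(logF = stats::plogis(z, log.p = TRUE), dlogF = stats::plogis(-z))
      }
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
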