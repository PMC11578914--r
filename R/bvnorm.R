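## Bivariate standard normal CDF and the cell-probability derivatives used by
## the polychoric likelihood. The CDF uses the single-integral representation
##   P(X <= h, Y <= k) = Phi(h)Phi(k) +
##       (1/2pi) * int_0^{asin(rho)} exp(-(h^2 + k^2 - 2hk sin t)/(2 cos^2 t)) dt
## whose integrand is smooth for all |rho| < 1, evaluated by fixed Gauss-Legendre
## quadrature. Accuracy is ~1e-10 for |rho| <= 0.99, ample for likelihoods that
## are anyway clipped to |rho| <= 0.999.

.ordinvar_cache <- new.env(parent = emptyenv())

.glNodes <- function() {
  if (is.null(.ordinvar_cache$gl)) {
    ## 24 nodes give ~3e-12 absolute error over |rho| <= 0.99
    gl <- pracma::gaussLegendre(24, 0, 1)
    .ordinvar_cache$gl <- list(x = gl$x, w = gl$w)
  }
  .ordinvar_cache$gl
}

#' Bivariate standard normal distribution function
#'
#' Lower-tail probability \eqn{P(X \le h, Y \le k)} for a standard bivariate
#' normal vector with correlation \code{rho}. Vectorized over \code{h} and
#' \code{k} (recycled); \code{rho} must be a scalar with \eqn{|\rho| < 1}.
#' Infinite bounds are handled (reducing to the univariate marginal or 0).
#'
#' @param h,k upper integration limits (may be \code{-Inf}/\code{Inf}).
#' @param rho correlation, \eqn{|\rho| < 1}.
#' @return numeric vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  if (length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1)
    stop("'rho' must be a single value with |rho| < 1")
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  ## +-8.3 saturates pnorm well below 1e-16; maps infinities safely
  hc <- pmin(pmax(h, -8.3), 8.3)
  kc <- pmin(pmax(k, -8.3), 8.3)
  base <- stats::pnorm(hc) * stats::pnorm(kc)
  if (rho == 0) return(base)
  gl <- .glNodes()
  a <- asin(rho)
  tt <- a * gl$x                      # nodes on [0, asin(rho)]
  st <- sin(tt); c2 <- cos(tt)^2
  ## integrand matrix: n points x nodes
  num <- outer(hc^2 + kc^2, rep(1, length(tt))) - 2 * outer(hc * kc, st)
  integ <- exp(-num / (2 * rep(c2, each = n)))
  base + (a / (2 * pi)) * as.vector(integ %*% gl$w)
}

## bivariate normal density; 0 at infinite arguments
.dbvnorm <- function(h, k, rho) {
  out <- numeric(max(length(h), length(k)))
  h <- rep_len(h, length(out)); k <- rep_len(k, length(out))
  fin <- is.finite(h) & is.finite(k)
  s2 <- 1 - rho^2
  out[fin] <- exp(-(h[fin]^2 - 2 * rho * h[fin] * k[fin] + k[fin]^2) / (2 * s2)) /
    (2 * pi * sqrt(s2))
  out
}

## Cell probabilities of a C1 x C2 ordinal table implied by thresholds tau1,
## tau2 and latent correlation rho. Returns a matrix [C1, C2].
.cellProbs <- function(tau1, tau2, rho) {
  t1 <- c(-Inf, tau1, Inf); t2 <- c(-Inf, tau2, Inf)
  B <- matrix(pbvnorm(rep(t1, times = length(t2)), rep(t2, each = length(t1)), rho),
              nrow = length(t1))
  P <- B[-1, -1, drop = FALSE] - B[-nrow(B), -1, drop = FALSE] -
    B[-1, -ncol(B), drop = FALSE] + B[-nrow(B), -ncol(B), drop = FALSE]
  pmax(P, 0)
}

## d cellProbs / d rho via Plackett's identity: rectangle sum of densities.
.dcellProbs_drho <- function(tau1, tau2, rho) {
  t1 <- c(-Inf, tau1, Inf); t2 <- c(-Inf, tau2, Inf)
  D <- matrix(.dbvnorm(rep(t1, times = length(t2)), rep(t2, each = length(t1)), rho),
              nrow = length(t1))
  D[-1, -1, drop = FALSE] - D[-nrow(D), -1, drop = FALSE] -
    D[-1, -ncol(D), drop = FALSE] + D[-nrow(D), -ncol(D), drop = FALSE]
}

## d cellProbs / d tau1[c]: phi(tau1c) * [Phi(cond(b)) - Phi(cond(b-1))] on the
## cells adjacent to threshold c. Returns a list over c of [C1, C2] matrices.
.dcellProbs_dtau1 <- function(tau1, tau2, rho) {
  C1 <- length(tau1) + 1L; C2 <- length(tau2) + 1L
  t2 <- c(-Inf, tau2, Inf)
  s <- sqrt(1 - rho^2)
  lapply(seq_along(tau1), function(cc) {
    tc <- tau1[cc]
    cond <- stats::pnorm((t2 - rho * tc) / s)     # length C2+1
    band <- stats::dnorm(tc) * (cond[-1] - cond[-length(cond)])  # length C2
    M <- matrix(0, C1, C2)
    M[cc, ] <- band          # upper cell row gains
    M[cc + 1L, ] <- -band    # next row loses
    M
  })
}
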