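# Tail probabilities of positive-definite quadratic forms in normal variables:
# P(sum_k lambda_k chi^2_1 >= q). Primary route is characteristic-function
# inversion (Imhof's integral); the far tail is refined by a Lugannani-Rice
# saddlepoint approximation, and a moment-matched non-central scaled
# chi-square (Liu-Tang-Zhang) serves as the fallback when inversion fails.

imhof_integrand <- function(u, lambda, q) {
  # theta and rho of Imhof's formula, vectorised over u
  theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
  logrho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
  sin(theta) * exp(-logrho) / u
}

imhof_pvalue <- function(lambda, q, tol = 1e-8, max_points = 2e6) {
  # Equally spaced midpoint rule on Imhof's integral. For characteristic
  # function inversion the discretisation error of an equal-step rule is an
  # aliasing error bounded by the tail mass of the distribution beyond
  # 2*pi/step, not by the oscillation of the integrand, so the step is set
  # from a chi-square tail bound (Q <= max(lambda) * chisq_m stochastically)
  # and the truncation point U from the integrand's amplitude envelope
  # |integrand| <= u^(-1 - m/2) / prod(lambda)^(1/2).
  m <- length(lambda)
  sl <- 0.5 * sum(log(lambda))
  # truncation point: beyond the last stationary point of the phase the
  # integrand oscillates at frequency >= q/2 under the amplitude envelope
  # u^(-1 - m/2) * exp(-sl), so the tail is bounded by the stationary-phase
  # estimate (envelope / phase-derivative); fall back to the raw envelope
  # bound if it is tighter
  u_star <- sqrt(max(sum(lambda) / q - 1, 0)) / min(lambda)
  U_osc <- (4 * exp(-sl) / (m * pi * tol * q))^(1 / (m / 2 + 1))
  U_env <- (2 * exp(-sl) / (m * pi * tol))^(2 / m)
  U <- max(min(U_osc, U_env), 2 * u_star)
  K <- max(lambda) * stats::qchisq(tol, df = m, lower.tail = FALSE) +
    max(q, sum(lambda))
  delta <- 2 * pi / K
  N <- max(ceiling(U / delta), 256L)
  trunc_err <- tol
  if (N > max_points) {
    N <- max_points
    U <- N * delta
    trunc_err <- 2 * exp(-sl) / (m * pi) * U^(-m / 2)
  }
  val <- 0
  chunk <- 200000L
  for (start in seq(0L, N - 1L, by = chunk)) {
    idx <- start + seq_len(min(chunk, N - start))
    u <- (idx - 0.5) * delta
    val <- val + sum(imhof_integrand(u, lambda, q))
  }
  p <- 0.5 + val * delta / pi
  attr(p, "abs.error") <- trunc_err + tol
  p
}

saddlepoint_pvalue <- function(lambda, q) {
  # Kuonen's saddlepoint for Q = sum lambda_k chi^2_1; K(t) = -1/2 sum
  # log(1 - 2 t lambda). Unstable when q is at the mean (t -> 0).
  if (abs(q - sum(lambda)) < 1e-8 * sum(lambda)) return(NA_real_)
  kprime <- function(t) colSums(lambda / (1 - 2 * outer(lambda, t)))
  tmax <- 1 / (2 * max(lambda))
  root <- try(stats::uniroot(function(t) kprime(t) - q,
                             lower = -1e3 / max(lambda),
                             upper = tmax - 1e-10 * tmax,
                             tol = 1e-12), silent = TRUE)
  if (inherits(root, "try-error")) return(NA_real_)
  t <- root$root
  if (abs(t) < 1e-10) return(NA_real_)
  K <- -0.5 * sum(log1p(-2 * t * lambda))
  K2 <- sum(2 * lambda^2 / (1 - 2 * t * lambda)^2)
  w <- sign(t) * sqrt(2 * (t * q - K))
  v <- t * sqrt(K2)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), l = l, d = d,
       muX = l + d, sigmaX = sqrt(2) * a)
}

liu_pvalue <- function(lambda, q, params = liu_params(lambda)) {
  tstar <- (q - params$muQ) / params$sigmaQ
  stats::pchisq(tstar * params$sigmaX + params$muX, df = params$l,
                ncp = params$d, lower.tail = FALSE)
}

# quantile of the mixture at upper-tail probability p, by Liu moment matching
liu_quantile <- function(p, params) {
  x <- stats::qchisq(p, df = params$l, ncp = params$d, lower.tail = FALSE)
  (x - params$muX) / params$sigmaX * params$sigmaQ + params$muQ
}

#' Upper tail probability of a weighted sum of 1-df chi-squares
#'
#' Computes `P(sum_k lambda_k chi^2_1k >= statistic)`, the null tail of the
#' score-type quadratic forms underlying variance-component and omnibus
#' rare-variant tests.
#'
#' Equal eigenvalues reduce exactly to a scaled central chi-square and are
#' evaluated in closed form. Otherwise the characteristic function is
#' inverted numerically (Imhof's integral); results in the far tail, where
#' oscillatory quadrature loses relative accuracy, are refined by a
#' saddlepoint approximation, and a moment-matched scaled chi-square is the
#' fallback when inversion fails. The returned value is clamped to
#' `(floor, 1]` so a p-value of exactly zero is never reported.
#'
#' @param lambda non-negative eigenvalues; at least one must be positive.
#' @param statistic observed value of the quadratic form.
#' @param method `"auto"` (default), `"cf"` (inversion only), `"saddlepoint"`,
#'   or `"moment"`.
#' @param floor smallest reportable p-value (default `1e-30`).
#' @return a p-value in `(0, 1]`, with attribute `method` naming the route
#'   that produced it.
#' @export
quad_form_pvalue <- function(lambda, statistic,
                             method = c("auto", "cf", "saddlepoint", "moment"),
                             floor = 1e-30) {
  method <- match.arg(method)
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  if (length(lambda) == 0L || all(lambda <= 0)) {
    stop("all eigenvalues are zero; the quadratic form is degenerate")
  }
  if (statistic <= 0) return(structure(1, method = "degenerate"))
  finish <- function(p, how) {
    structure(min(1, max(floor, p)), method = how)
  }
  # exact scaled chi-square when all eigenvalues coincide
  if (diff(range(lambda)) < 1e-12 * max(lambda) && method != "moment") {
    p <- stats::pchisq(statistic / lambda[1], df = length(lambda),
                       lower.tail = FALSE)
    return(finish(p, "exact_chisq"))
  }
  if (method == "moment") return(finish(liu_pvalue(lambda, statistic), "moment"))
  if (method == "saddlepoint") {
    p <- saddlepoint_pvalue(lambda, statistic)
    if (!is.finite(p)) p <- liu_pvalue(lambda, statistic)
    return(finish(p, "saddlepoint"))
  }
  p <- imhof_pvalue(lambda, statistic)
  err <- attr(p, "abs.error")
  if (is.null(err) || !is.finite(err)) err <- Inf
  # trust inversion only where its error bound is small relative to p;
  # below that the saddlepoint has far better relative accuracy
  ok <- is.finite(p) && p > 1e-6 && p <= 1 && err < 0.01 * p
  if (method == "cf") {
    if (!is.finite(p)) return(finish(liu_pvalue(lambda, statistic), "moment"))
    return(finish(as.numeric(p), "cf"))
  }
  if (ok) return(finish(as.numeric(p), "cf"))
  sp <- saddlepoint_pvalue(lambda, statistic)
  if (is.finite(sp)) return(finish(sp, "saddlepoint"))
  if (is.finite(p) && p > 0) return(finish(as.numeric(p), "cf"))
  finish(liu_pvalue(lambda, statistic), "moment")
}
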