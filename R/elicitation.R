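# Expert-elicitation computations: turning hypothetical-patient transition
# counts and roulette ("chips and bins") histograms into the parameter
# distributions used deterministically and in the PSA.

#' Distribution parameter container
#'
#' Light S3 wrapper for the families the model uses: `beta` (alpha, beta),
#' `dirichlet` (concentration vector), `gamma` (shape, scale) and `fixed`
#' (a degenerate point mass).
#'
#' @param family one of `"beta"`, `"dirichlet"`, `"gamma"`, `"fixed"`.
#' @param ... family parameters, see Details.
#' @return An object of class `ep_dist`.
#' @export
ep_dist <- function(family = c("beta", "dirichlet", "gamma", "fixed"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  x <- switch(family,
    beta = {
      stopifnot(is.numeric(pars$alpha), is.numeric(pars$beta))
      if (pars$alpha <= 0 || pars$beta <= 0)
        stop("beta parameters must be > 0", call. = FALSE)
      list(family = "beta", alpha = pars$alpha, beta = pars$beta)
    },
    dirichlet = {
      a <- pars$alpha
      if (!is.numeric(a) || length(a) < 2 || any(a <= 0))
        stop("dirichlet concentrations must be a numeric vector (length >= 2) of positives",
             call. = FALSE)
      list(family = "dirichlet", alpha = a)
    },
    gamma = {
      if (pars$shape <= 0 || pars$scale <= 0)
        stop("gamma shape and scale must be > 0", call. = FALSE)
      list(family = "gamma", shape = pars$shape, scale = pars$scale)
    },
    fixed = list(family = "fixed", value = pars$value)
  )
  structure(x, class = "ep_dist")
}

#' @export
print.ep_dist <- function(x, ...) {
  p <- switch(x$family,
    beta = sprintf("alpha=%g, beta=%g (mean %.6g)", x$alpha, x$beta,
                   x$alpha / (x$alpha + x$beta)),
    dirichlet = paste0("alpha=(", paste(signif(x$alpha, 6), collapse = ", "), ")"),
    gamma = sprintf("shape=%g, scale=%g (mean %g)", x$shape, x$scale,
                    x$shape * x$scale),
    fixed = sprintf("value=%g", x$value))
  cat("<ep_dist ", x$family, "> ", p, "\n", sep = "")
  invisible(x)
}

#' Mean of an elicited distribution
#' @param x an [ep_dist()] object.
#' @return Numeric mean (a vector for Dirichlet).
#' @export
ep_dist_mean <- function(x) {
  switch(x$family,
    beta = x$alpha / (x$alpha + x$beta),
    dirichlet = x$alpha / sum(x$alpha),
    gamma = x$shape * x$scale,
    fixed = x$value)
}

#' Draw samples from an elicited distribution
#'
#' Beta and Gamma draws use the corresponding `stats` samplers; Dirichlet
#' vectors are drawn as normalised independent Gamma(alpha_i, 1) variates.
#'
#' @param x an [ep_dist()] object.
#' @param n number of draws.
#' @return For scalar families a numeric vector of length `n`; for Dirichlet
#'   an `n` x k matrix whose rows sum to 1.
#' @export
ep_dist_sample <- function(x, n = 1) {
  switch(x$family,
    beta = stats::rbeta(n, x$alpha, x$beta),
    gamma = stats::rgamma(n, shape = x$shape, scale = x$scale),
    fixed = rep(x$value, n),
    dirichlet = {
      k <- length(x$alpha)
      g <- matrix(stats::rgamma(n * k, shape = rep(x$alpha, each = n)), nrow = n)
      m <- g / rowSums(g)
      colnames(m) <- names(x$alpha)
      m
    })
}

#' Fit a Beta distribution to a binomial transition count
#'
#' The elicitation assigned 1000 hypothetical patients to a health state and
#' asked how many move to the single destination state within one month. The
#' natural conjugate summary is Beta(alpha = movers, beta = stayers), whose
#' mean is the elicited monthly transition probability. Fractional
#' pseudo-counts are accepted (the elicited tables use counts such as 0.1).
#'
#' @param k number (possibly fractional) of patients moving.
#' @param n cohort size (> 0).
#' @return An [ep_dist()] of family `beta`, or family `fixed` at 0 or 1 when
#'   the count is degenerate (with a warning): a Beta with a zero parameter
#'   is not a proper distribution.
#' @export
#' @examples
#' fit_beta_from_counts(3, 1000)      # mean 0.003
#' fit_beta_from_counts(0.1, 1000)    # Beta(0.1, 999.9)
fit_beta_from_counts <- function(k, n) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1 || length(n) != 1)
    stop("k and n must be scalars", call. = FALSE)
  if (n <= 0) stop("cohort size n must be > 0", call. = FALSE)
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  if (k == 0) {
    warning("zero movers: degenerate Beta replaced by a point mass at 0")
    return(ep_dist("fixed", value = 0))
  }
  if (k == n) {
    warning("all patients move: degenerate Beta replaced by a point mass at 1")
    return(ep_dist("fixed", value = 1))
  }
  ep_dist("beta", alpha = k, beta = n - k)
}

#' Fit a Dirichlet distribution to a multinomial transition count
#'
#' For origin states with two or more exit destinations the monthly counts
#' form a multinomial over (stay, destination_1, destination_2, ...); the
#' conjugate summary is a Dirichlet whose concentrations are those counts.
#'
#' @param exits named numeric vector of per-destination monthly counts
#'   (length >= 2; fractional counts allowed).
#' @param n cohort size; the stay concentration is `n - sum(exits)`.
#' @return An [ep_dist()] of family `dirichlet` with concentrations
#'   `(stay, exits...)`.
#' @export
#' @examples
#' fit_dirichlet_from_counts(c(no_pain = 2, moderate = 2), 1000)
fit_dirichlet_from_counts <- function(exits, n) {
  if (length(exits) < 2)
    stop("a single destination is binomial: use fit_beta_from_counts()",
         call. = FALSE)
  if (any(exits < 0)) stop("counts must be >= 0", call. = FALSE)
  stay <- n - sum(exits)
  if (stay <= 0) stop("exit counts exceed the cohort size", call. = FALSE)
  a <- c(stay = stay, exits)
  ep_dist("dirichlet", alpha = a)
}

#' Fit a Beta distribution to a roulette ("chips and bins") histogram
#'
#' The expert allocates chips across utility bins; the histogram is summarised
#' by its chips-weighted mean and variance at bin midpoints and mapped to a
#' Beta by the method of moments:
#' `nu = m (1 - m) / v - 1`, `alpha = m nu`, `beta = (1 - m) nu`.
#'
#' A histogram with all chips in one bin has zero midpoint variance but still
#' implies within-bin uncertainty, so the variance is floored at the variance
#' of a uniform spread over one bin, `width^2 / 12`.
#'
#' @param bins data frame with columns `bin_low`, `bin_high`, `chips`
#'   (non-negative integers; edges strictly increasing within `[0, 1]`).
#' @return An [ep_dist()] of family `beta`.
#' @export
#' @examples
#' h <- data.frame(bin_low = c(0.6, 0.7, 0.8), bin_high = c(0.7, 0.8, 0.9),
#'                 chips = c(2, 5, 3))
#' fit_beta_from_roulette(h)
fit_beta_from_roulette <- function(bins) {
  req <- c("bin_low", "bin_high", "chips")
  if (!all(req %in% names(bins)))
    stop("bins needs columns bin_low, bin_high, chips", call. = FALSE)
  if (nrow(bins) < 2) stop("need at least 2 bins", call. = FALSE)
  if (any(bins$chips < 0) || sum(bins$chips) < 1)
    stop("chips must be non-negative with at least one chip placed", call. = FALSE)
  if (any(bins$bin_low < 0) || any(bins$bin_high > 1) ||
      any(bins$bin_high <= bins$bin_low))
    stop("bin edges must be strictly increasing within [0, 1]", call. = FALSE)
  mid <- (bins$bin_low + bins$bin_high) / 2
  w <- bins$chips / sum(bins$chips)
  m <- sum(w * mid)
  v <- sum(w * (mid - m)^2)
  occupied <- bins$chips > 0
  floor_v <- max(((bins$bin_high - bins$bin_low)[occupied])^2) / 12
  v <- max(v, floor_v)
  if (v >= m * (1 - m))
    stop("histogram variance is too large for a Beta on [0, 1]; ",
         "use narrower support or more bins", call. = FALSE)
  nu <- m * (1 - m) / v - 1
  ep_dist("beta", alpha = m * nu, beta = (1 - m) * nu)
}

#' Gamma distribution from a published mean and an assumed coefficient of variation
#'
#' Unit costs are published as point estimates with a Gamma distribution
#' named for the PSA but no spread; the conventional completion is a Gamma
#' with the published mean and an assumed CV:
#' `shape = 1 / cv^2`, `scale = mean * cv^2`.
#'
#' @param mean published mean (> 0), GBP.
#' @param cv coefficient of variation (> 0); default 0.2.
#' @return An [ep_dist()] of family `gamma` with the requested mean and
#'   standard deviation `mean * cv`.
#' @export
#' @examples
#' gamma_from_mean_cv(26.67, 0.2)  # shape 25, scale 1.0668
gamma_from_mean_cv <- function(mean, cv = 0.2) {
  if (mean <= 0 || cv <= 0) stop("mean and cv must be > 0", call. = FALSE)
  ep_dist("gamma", shape = 1 / cv^2, scale = mean * cv^2)
}
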