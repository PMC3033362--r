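#' Per-neuron degree, strength, and multiplicity summary
#'
#' Binary statistics (degree, in/out-degree) are computed on A > 0;
#' strength statistics count synaptic terminals, i.e. summed multiplicities.
#' For a directed network \code{in_number}/\code{out_number} are the
#' weighted in/out-strengths; undirected networks report \code{degree} and
#' \code{strength} only. The per-connection multiplicity list (each
#' connection once) is attached as the \code{multiplicities} attribute.
#'
#' @param net an \code{adjacency_network}.
#' @return data.frame indexed by neuron; attribute \code{multiplicities}.
#' @export
degree_summary <- function(net) {
  A <- net$weights
  B <- (A > 0) * 1
  if (net$directed) {
    out <- data.frame(name = net$names,
                      in_degree = colSums(B), out_degree = rowSums(B),
                      degree = colSums((B | t(B)) * 1),
                      in_number = colSums(A), out_number = rowSums(A),
                      strength = colSums(A) + rowSums(A),
                      row.names = net$names, stringsAsFactors = FALSE)
    mult <- A[A > 0]
  } else {
    out <- data.frame(name = net$names, degree = rowSums(B),
                      strength = rowSums(A),
                      row.names = net$names, stringsAsFactors = FALSE)
    mult <- A[A > 0 & upper.tri(A)]
  }
  attr(out, "multiplicities") <- as.numeric(mult)
  out
}

#' Empirical survival function P(X >= k)
#'
#' The complement of the cumulative distribution function; preferred for
#' visualizing heavy tails because no histogram binning is required.
#'
#' @param values non-negative integers (multiset).
#' @param k optional evaluation points; default is every observed value
#'   plus max + 1.
#' @return data.frame with columns \code{k} and \code{F}.
#' @export
survival_function <- function(values, k = NULL) {
  if (!length(values)) stop("survival_function needs non-empty input")
  if (is.null(k)) k <- c(sort(unique(values)), max(values) + 1)
  F <- vapply(k, function(x) mean(values >= x), numeric(1))
  data.frame(k = k, F = F)
}

# Hurwitz zeta  sum_{j>=0} (q + j)^(-s)  by Euler-Maclaurin (s > 1);
# vectorized over q
hurwitz_zeta <- function(s, q) {
  N <- 64
  j <- 0:(N - 1)
  head_sum <- colSums(outer(j, q, `+`)^(-s))
  a <- q + N
  head_sum + a^(1 - s) / (s - 1) + 0.5 * a^(-s) +
    s / 12 * a^(-s - 1) - s * (s + 1) * (s + 2) / 720 * a^(-s - 3)
}

# discrete power-law log-likelihood on the tail x >= xmin
pl_loglik <- function(alpha, x, xmin) {
  -alpha * sum(log(x)) - length(x) * log(hurwitz_zeta(alpha, xmin))
}

pl_fit_alpha <- function(x, xmin) {
  opt <- optimize(function(a) pl_loglik(a, x, xmin),
                  interval = c(1.000001, 20), maximum = TRUE)
  list(alpha = opt$maximum, loglik = opt$objective)
}

# discrete exponential (geometric on {xmin, xmin+1, ...}): closed-form MLE
exp_fit_rate <- function(x, xmin) {
  m <- mean(x - xmin)
  q <- m / (1 + m)                       # e^{-mu}
  mu <- -log(q)
  ll <- length(x) * log(1 - q) + sum((x - xmin) * log(q))
  list(rate = mu, loglik = ll)
}

# model CDF on the tail support, P(X <= k | X >= xmin)
tail_cdf <- function(fit, k, xmin) {
  if (fit$family == "power_law") {
    1 - hurwitz_zeta(fit$params[["alpha"]], k + 1) /
      hurwitz_zeta(fit$params[["alpha"]], xmin)
  } else {
    q <- exp(-fit$params[["rate"]])
    1 - q^(k - xmin + 1)
  }
}

ks_stat <- function(fit, x, xmin) {
  tail <- sort(x[x >= xmin])
  ks <- sort(unique(tail))
  emp <- cumsum(tabulate(match(tail, ks))) / length(tail)
  mod <- tail_cdf(fit, ks, xmin)
  max(abs(emp - mod))
}

new_tail_fit <- function(family, params, xmin, ks, loglik, n_tail,
                         gof_pvalue = NA_real_) {
  structure(list(family = family, params = params, xmin = xmin, ks = ks,
                 loglik = loglik, n_tail = n_tail, gof_pvalue = gof_pvalue),
            class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("tail_fit: %s, xmin = %g, n_tail = %d\n  params: %s\n  KS = %.4g, loglik = %.4g%s\n",
              x$family, x$xmin, x$n_tail,
              paste(names(x$params), signif(unlist(x$params), 4),
                    sep = " = ", collapse = ", "),
              x$ks, x$loglik,
              if (is.na(x$gof_pvalue)) "" else
                sprintf(", gof p = %.3f", x$gof_pvalue)))
  invisible(x)
}

#' Fit the tail of a discrete distribution by maximum likelihood
#'
#' For each candidate fit start xmin, the family parameter is obtained by
#' maximizing the discrete log-likelihood on the tail (power law normalized
#' by the Hurwitz zeta function; exponential decay as a geometric law); the
#' xmin actually reported is the one minimizing the Kolmogorov-Smirnov
#' distance between the fitted and empirical tail distributions.
#'
#' @param values positive integers.
#' @param family \code{"power_law"} or \code{"exponential"}.
#' @param min_tail minimum number of tail observations for a candidate
#'   xmin (default 10).
#' @return a \code{tail_fit} object.
#' @export
fit_tail <- function(values, family = c("power_law", "exponential"),
                     min_tail = 10) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (any(values < 1)) stop("tail fitting expects values >= 1")
  cand <- sort(unique(values))
  # a candidate xmin must leave a tail with >= min_tail distinct values and
  # at least as many observations, else the KS minimization favours
  # vanishing tails
  cand <- cand[vapply(cand, function(xm)
    length(unique(values[values >= xm])), 1) >= min_tail &
    vapply(cand, function(xm) sum(values >= xm), 1) >= min_tail]
  if (!length(cand))
    stop("degenerate tail: need >= ", min_tail, " distinct tail values")
  best <- NULL
  for (xm in cand) {
    x <- values[values >= xm]
    f <- if (family == "power_law") {
      pf <- pl_fit_alpha(x, xm)
      new_tail_fit("power_law", list(alpha = pf$alpha), xm, NA, pf$loglik,
                   length(x))
    } else {
      ef <- exp_fit_rate(x, xm)
      new_tail_fit("exponential", list(rate = ef$rate), xm, NA, ef$loglik,
                   length(x))
    }
    f$ks <- ks_stat(f, values, xm)
    if (is.null(best) || f$ks < best$ks) best <- f
  }
  best
}

# draw from the fitted tail model
rtail_model <- function(fit, n) {
  if (fit$family == "exponential") {
    fit$xmin + rgeom(n, 1 - exp(-fit$params[["rate"]]))
  } else {
    # inverse-CDF by binary search on the zeta survival function
    alpha <- fit$params[["alpha"]]
    z0 <- hurwitz_zeta(alpha, fit$xmin)
    u <- runif(n)
    lo <- rep(fit$xmin, n)
    hi <- rep(fit$xmin, n)
    # P(X >= k) = zeta(alpha, k) / z0; grow hi until survival < u
    surv <- function(k) hurwitz_zeta(alpha, k) / z0
    for (i in seq_len(n)) {
      while (surv(hi[i] + 1) > u[i]) hi[i] <- max(hi[i] * 2, hi[i] + 1)
      while (hi[i] > lo[i]) {
        mid <- (lo[i] + hi[i] + 1) %/% 2
        if (surv(mid) > u[i]) lo[i] <- mid else hi[i] <- mid - 1
      }
    }
    lo
  }
}

#' Bootstrap goodness-of-fit p-value for a tail fit
#'
#' Semiparametric bootstrap: each replicate dataset draws, for every
#' observation, either from the fitted tail model (with probability
#' n_tail / n) or uniformly from the observed body below xmin; the replicate
#' is refit (including re-selection of xmin) and the p-value is the
#' fraction of replicates whose KS statistic is at least the observed one.
#' By convention p > 0.1 is read as a plausible fit.
#'
#' @param fit a \code{tail_fit}.
#' @param values the data the fit was computed from.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed optional seed.
#' @return the fit with \code{gof_pvalue} filled in.
#' @export
gof_pvalue <- function(fit, values, n_boot = 1000, seed = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  body <- values[values < fit$xmin]
  p_tail <- fit$n_tail / n
  ge <- 0
  for (b in seq_len(n_boot)) {
    from_tail <- runif(n) < p_tail
    x <- numeric(n)
    nt <- sum(from_tail)
    if (nt) x[from_tail] <- rtail_model(fit, nt)
    if (n - nt) x[!from_tail] <- sample(body, n - nt, replace = TRUE)
    rf <- try(fit_tail(x, fit$family, min_tail = min(fit$n_tail, 10)),
              silent = TRUE)
    if (inherits(rf, "try-error")) next
    if (rf$ks >= fit$ks) ge <- ge + 1
  }
  fit$gof_pvalue <- ge / n_boot
  fit
}

#' Fit the discrete stretched-exponential (Weibull) multiplicity law
#'
#' Fits P(M >= m) = exp(-((m - 1)/lambda)^beta) for m >= 1 to the whole
#' distribution (not a tail) by maximum likelihood over (lambda, beta).
#'
#' @param values positive integers.
#' @return a \code{tail_fit} with family \code{"stretched_exponential"}.
#' @export
fit_stretched_exponential <- function(values) {
  values <- as.numeric(values)
  if (any(values < 1)) stop("values must be >= 1")
  if (length(unique(values)) < 2)
    stop("degenerate data: stretched-exponential shape is unidentifiable")
  nll <- function(par) {
    lambda <- exp(par[1]); beta <- exp(par[2])
    sm <- exp(-((values - 1) / lambda)^beta)   # P(M >= m)
    sm1 <- exp(-(values / lambda)^beta)        # P(M >= m + 1)
    p <- pmax(sm - sm1, 1e-300)
    -sum(log(p))
  }
  opt <- optim(c(log(max(mean(values) - 1, 0.1)), 0), nll,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  lambda <- exp(opt$par[1]); beta <- exp(opt$par[2])
  fit <- new_tail_fit("stretched_exponential",
                      list(lambda = lambda, beta = beta),
                      xmin = 1, ks = NA, loglik = -opt$value,
                      n_tail = length(values))
  sm <- function(k) exp(-((k - 1) / lambda)^beta)
  ks <- sort(unique(values))
  emp <- vapply(ks, function(k) mean(values <= k), 1)
  fit$ks <- max(abs(emp - (1 - sm(ks + 1))))
  fit
}

#' Compare two tail fits by log-likelihood on a common support
#'
#' Both families are re-fit on the tail starting at the smaller of the two
#' selected xmin values, so their log-likelihoods are computed on the same
#' observations and are commensurable. (Using the larger xmin instead
#' makes the comparison depend on a possibly tiny tail selected by the
#' misspecified family, and empirically turns the preference into a coin
#' flip; see the methods vignette.)
#'
#' @param fit_a,fit_b \code{tail_fit} objects of different families.
#' @param values the shared data.
#' @return list with \code{preferred}, \code{delta_loglik}
#'   (loglik_a - loglik_b on the common tail), and the two re-fits.
#' @export
compare_fits <- function(fit_a, fit_b, values) {
  xmin <- min(fit_a$xmin, fit_b$xmin)
  refit <- function(fit) {
    x <- values[values >= xmin]
    switch(fit$family,
      power_law = {
        pf <- pl_fit_alpha(x, xmin)
        new_tail_fit("power_law", list(alpha = pf$alpha), xmin, NA,
                     pf$loglik, length(x))
      },
      exponential = {
        ef <- exp_fit_rate(x, xmin)
        new_tail_fit("exponential", list(rate = ef$rate), xmin, NA,
                     ef$loglik, length(x))
      },
      stretched_exponential = {
        f <- fit_stretched_exponential(x - xmin + 1)
        f$xmin <- xmin
        f
      })
  }
  a <- refit(fit_a)
  b <- refit(fit_b)
  delta <- a$loglik - b$loglik
  list(preferred = if (delta >= 0) a$family else b$family,
       delta_loglik = delta, fit_a = a, fit_b = b)
}

#' Correlation between two sequences with a two-sided test
#'
#' @param x,y numeric sequences of equal length (>= 3).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with \code{r} and \code{p_value}.
#' @export
sequence_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    stop("sequences must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in a sequence")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
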