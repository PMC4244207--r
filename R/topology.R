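#' Degree distribution of a network
#'
#' @param net A `gene_network` object.
#' @return Data frame `degree` (observed positive degrees, ascending) and
#'   `rel_freq` (fraction of nodes at that degree; sums to 1).
#' @export
degree_distribution <- function(net) {
  k <- node_degrees(net)
  tab <- table(k)
  data.frame(degree = as.integer(names(tab)),
             rel_freq = as.numeric(tab) / length(k))
}

fit_one_model <- function(formula, data, start, lower = NULL) {
  try_fit <- function(st) tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = st,
                      lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  fit <- try_fit(start)
  if (inherits(fit, "error"))  # e.g. singular gradient at an exact start
    fit <- try_fit(lapply(start, function(v) v * 1.05 + 1e-3))
  if (inherits(fit, "error"))
    return(list(params = lapply(start, function(x) NA_real_),
                r_squared = NA_real_, converged = FALSE,
                message = conditionMessage(fit)))
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((data$y - mean(data$y))^2)
  list(params = as.list(coef(fit)), r_squared = 1 - ss_res / ss_tot,
       converged = TRUE, message = NULL)
}

#' Fit lognormal, power-law and exponential degree-distribution models
#'
#' Nonlinear least squares of the relative frequency y against degree x for
#' three candidate models:
#' lognormal `y = y0 + A/(sqrt(2 pi) sigma x) exp(-(ln x - mu)^2/(2 sigma^2))`,
#' power law `y = a x^b`, and exponential `y = y0 + A exp(b x)`.
#' Fits are performed on the raw (unbinned) relative-frequency points;
#' starting values come from log-linear pre-fits; sigma and A are bounded
#' below by 0. A non-converging model is flagged (`converged = FALSE`)
#' rather than raised as an error. The best model maximises R-squared.
#'
#' @param dd Data frame from [degree_distribution] (columns `degree`,
#'   `rel_freq`), with at least 5 distinct degrees.
#' @return A `degree_fits` object: list of the three fits (`params`,
#'   `r_squared`, `converged`) plus `best`, the name of the winning model.
#' @export
fit_degree_models <- function(dd) {
  if (nrow(dd) < 5L) stop_fgnet("need at least 5 distinct degrees to fit")
  d <- data.frame(x = as.numeric(dd$degree), y = dd$rel_freq)
  pos <- d$y > 0

  lf <- lm(log(d$y[pos]) ~ log(d$x[pos]))
  power <- fit_one_model(y ~ a * x^b, d,
                         start = list(a = exp(coef(lf)[[1]]),
                                      b = coef(lf)[[2]]))

  le <- lm(log(d$y[pos]) ~ d$x[pos])
  expo <- fit_one_model(y ~ y0 + A * exp(b * x), d,
                        start = list(y0 = 0, A = exp(coef(le)[[1]]),
                                     b = coef(le)[[2]]),
                        lower = c(y0 = -Inf, A = 1e-12, b = -Inf))

  mu0 <- sum(log(d$x) * d$y) / sum(d$y)
  sd0 <- sqrt(max(sum((log(d$x) - mu0)^2 * d$y) / sum(d$y), 0.1))
  logn <- fit_one_model(
    y ~ y0 + A / (sqrt(2 * pi) * sigma * x) *
      exp(-(log(x) - mu)^2 / (2 * sigma^2)),
    d, start = list(y0 = 0, mu = mu0, sigma = sd0, A = 1),
    lower = c(y0 = -Inf, mu = -Inf, sigma = 1e-6, A = 1e-12))

  fits <- list(lognormal = logn, power_law = power, exponential = expo)
  r2 <- vapply(fits, function(f)
    if (isTRUE(f$converged)) f$r_squared else -Inf, numeric(1))
  structure(c(fits, list(best = names(fits)[which.max(r2)])),
            class = "degree_fits")
}

#' @export
print.degree_fits <- function(x, ...) {
  cat("Degree-distribution model fits (best:", x$best, ")\n")
  for (m in c("lognormal", "power_law", "exponential")) {
    f <- x[[m]]
    if (isTRUE(f$converged)) {
      pars <- paste(sprintf("%s=%.4g", names(f$params), unlist(f$params)),
                    collapse = ", ")
      cat(sprintf("  %-12s R2 = %.5f  (%s)\n", m, f$r_squared, pars))
    } else {
      cat(sprintf("  %-12s did not converge: %s\n", m, f$message))
    }
  }
  invisible(x)
}

#' Joint degree distribution
#'
#' For every edge, the unordered pair (i, j) of its endpoint degrees gains
#' one count; the counts over all unordered degree pairs sum to the number
#' of edges.
#'
#' @param net A `gene_network` object.
#' @return Data frame `degree_i`, `degree_j` (i <= j), `count`.
#' @export
joint_degree_distribution <- function(net) {
  k <- node_degrees(net)
  if (!nrow(net$edges))
    return(data.frame(degree_i = integer(0), degree_j = integer(0),
                      count = integer(0)))
  di <- pmin(k[net$edges$from], k[net$edges$to])
  dj <- pmax(k[net$edges$from], k[net$edges$to])
  agg <- aggregate(list(count = rep(1L, length(di))),
                   by = list(degree_i = unname(di), degree_j = unname(dj)),
                   FUN = sum)
  agg[order(agg$degree_i, agg$degree_j), , drop = FALSE]
}

#' Mean neighbour degree per degree class (knn)
#'
#' For each observed degree k, the mean over nodes of that degree of the
#' mean degree of their neighbours. Unobserved degrees are skipped.
#'
#' @param net A `gene_network` object.
#' @return Data frame `degree`, `knn`.
#' @export
knn_curve <- function(net) {
  k <- node_degrees(net)
  g <- as_igraph(net)
  per_node <- vapply(net$nodes, function(v) {
    nb <- igraph::neighbors(g, v)$name
    if (!length(nb)) return(NA_real_)
    mean(k[nb])
  }, numeric(1))
  ok <- !is.na(per_node)
  agg <- aggregate(list(knn = per_node[ok]),
                   by = list(degree = unname(k[ok])), FUN = mean)
  agg[order(agg$degree), , drop = FALSE]
}

#' Pearson degree correlation (assortativity)
#'
#' The Pearson correlation of endpoint degrees over all edges, each
#' undirected edge contributing both orientations. A degree sequence with
#' zero variance at the edge ends (e.g. a k-regular graph) returns 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param net A `gene_network` object with at least one edge.
#' @return Scalar in \[-1, 1\].
#' @export
pearson_degree_correlation <- function(net) {
  if (!nrow(net$edges)) stop_fgnet("network has no edges")
  k <- node_degrees(net)
  x <- c(k[net$edges$from], k[net$edges$to])
  y <- c(k[net$edges$to], k[net$edges$from])
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  unname(cor(x, y))
}
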