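#' Feature vector of a network for simulation-based fitting
#'
#' Concatenates the descending-sorted degree sequence and the
#' descending-sorted local clustering sequence (length `2N`), a
#' label-invariant summary of the degree and clustering distributions
#' used as the response-side features of the PLS fit.
#'
#' @inheritParams network_density
#' @inheritParams clustering_coefficients
#' @return A numeric vector of length `2 N`.
#' @examples
#' network_features(igraph::make_ring(5))
#' @export
network_features <- function(net, isolates = c("zero", "exclude")) {
  g <- as_social_graph(net)
  cl <- clustering_coefficients(g, isolates = isolates)
  c(sort(igraph::degree(g), decreasing = TRUE),
    sort(unname(cl$local), decreasing = TRUE))
}

new_si_fit <- function(p_n_hat, p_r_hat, method, clipped, diagnostics) {
  structure(list(p_n_hat = p_n_hat, p_r_hat = p_r_hat, method = method,
                 clipped = clipped, diagnostics = diagnostics),
            class = "si_fit")
}

#' @export
print.si_fit <- function(x, ...) {
  cat(sprintf("<si_fit method=%s> p_n = %.4f, p_r = %.4f%s\n", x$method,
              x$p_n_hat, x$p_r_hat,
              if (x$clipped) " (clipped to [0, 1])" else ""))
  invisible(x)
}

#' @rdname fit_analytical
#' @param x a `si_fit` object.
#' @param ... unused.
#' @export
tidy.si_fit <- function(x, ...) {
  tibble::tibble(term = c("p_n", "p_r"),
                 estimate = c(x$p_n_hat, x$p_r_hat))
}

#' @rdname fit_analytical
#' @export
glance.si_fit <- function(x, ...) {
  tibble::tibble(p_n_hat = x$p_n_hat, p_r_hat = x$p_r_hat,
                 method = x$method, clipped = x$clipped)
}

#' Simulate a training ensemble for PLS fitting
#'
#' Draws `(p_n, p_r)` pairs uniformly on the unit square, simulates one
#' network per pair at size `n`, and stores the [network_features()]
#' matrix alongside the parameter draws. Building the ensemble once and
#' passing it to [fit_pls()] amortises the simulation cost across fits
#' to networks of the same size.
#'
#' @inheritParams simulate_network
#' @param n_sims number of parameter draws / simulated networks.
#' @return An object of class `si_pls_training`.
#' @export
build_pls_training <- function(n, n_sims = 10000, steps = max(2000, 10 * n),
                               p_b = 1, seed = NULL) {
  n_sims <- check_count(n_sims, "n_sims", min = 2L)
  if (!is.null(seed)) set.seed(seed)
  draws <- tibble::tibble(p_n = runif(n_sims), p_r = runif(n_sims))
  X <- matrix(NA_real_, n_sims, 2 * n)
  for (i in seq_len(n_sims)) {
    net <- simulate_network(n = n, p_n = draws$p_n[i], p_r = draws$p_r[i],
                            p_b = p_b, steps = steps)
    X[i, ] <- network_features(net)
  }
  colnames(X) <- c(sprintf("deg%03d", seq_len(n)), sprintf("cc%03d", seq_len(n)))
  structure(list(X = X, draws = draws, n = n, steps = steps, p_b = p_b,
                 seed = seed),
            class = "si_pls_training")
}

#' Fit (p_n, p_r) by PLS regression on simulated ensembles
#'
#' Simulates networks of the observed size across uniformly random
#' `(p_n, p_r)` values, regresses the parameters on the degree and
#' clustering feature vectors by partial least squares, and predicts the
#' parameters of the observed network from its own features. Features
#' are centred and unit-scaled before the regression; predictions are
#' clipped to \[0, 1\] with the clip recorded.
#'
#' Because the feature-to-parameter map is strongly nonlinear over the
#' full unit square, a single global linear fit carries region-dependent
#' bias. By default the regression is therefore localised: the
#' `local_size` training networks nearest the observed network in
#' standardised feature space are selected, and the PLS fit on that
#' neighbourhood linearises the map around the observation (the usual
#' regression-adjustment idea in simulation-based inference). Set
#' `local = FALSE` for the plain global regression, whose component
#' count is then chosen by 5-fold cross-validation on the training
#' ensemble.
#'
#' @inheritParams network_density
#' @param n_sims training simulations (ignored when `training` is
#'   given).
#' @param steps birth--death events per training simulation; defaults to
#'   `max(2000, 10 N)`.
#' @param components number of PLS components; the default is 2 (the
#'   parameter dimension) for the local fit and cross-validated for the
#'   global one.
#' @param local fit on the feature-space neighbourhood of the observed
#'   network rather than the full ensemble.
#' @param local_size neighbourhood size for the local fit.
#' @param max_components largest component count considered by the
#'   global fit's cross-validation.
#' @param seed optional integer seed for the training draws.
#' @param training optionally a prebuilt [build_pls_training()]
#'   ensemble matching the observed network's size.
#' @return A `si_fit` object; `tidy()` and `glance()` methods apply.
#' @export
fit_pls <- function(net, n_sims = 10000, steps = NULL, components = NULL,
                    local = TRUE, local_size = 100, max_components = 8,
                    seed = NULL, training = NULL) {
  if (!requireNamespace("mixOmics", quietly = TRUE)) {
    abort("fit_pls() requires the mixOmics package")
  }
  g <- as_social_graph(net)
  if (igraph::ecount(g) == 0) abort("cannot fit a network with no edges")
  n <- igraph::vcount(g)
  if (is.null(training)) {
    if (n_sims < 100) abort("`n_sims` must be at least 100")
    if (is.null(steps)) steps <- max(2000, 10 * n)
    training <- build_pls_training(n, n_sims = n_sims, steps = steps,
                                   seed = seed)
  } else {
    if (!inherits(training, "si_pls_training")) {
      abort("`training` must come from build_pls_training()")
    }
    if (training$n != n) {
      abort("`training` was built for a different network size")
    }
  }
  X <- training$X
  Y <- as.matrix(training$draws)
  obs <- network_features(g)
  if (local) {
    local_size <- min(local_size, nrow(X))
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv == 0] <- 1
    d2 <- colSums((t(sweep(sweep(X, 2, mu), 2, sdv, "/")) -
                     (obs - mu) / sdv)^2)
    idx <- order(d2)[seq_len(local_size)]
    X <- X[idx, , drop = FALSE]
    Y <- Y[idx, , drop = FALSE]
    if (is.null(components)) components <- 2L
  } else if (is.null(components)) {
    components <- cv_pls_components(X, Y, max_components)
  }
  fit <- mixOmics::pls(X, Y, ncomp = components, mode = "regression")
  obs_m <- matrix(obs, nrow = 1, dimnames = list(NULL, colnames(X)))
  pred <- predict(fit, obs_m)$predict[1, , components]
  clipped <- any(pred < 0 | pred > 1)
  est <- pmin(pmax(pred, 0), 1)
  new_si_fit(est[["p_n"]], est[["p_r"]], "pls", clipped,
             list(n_sims = nrow(training$X), components = components,
                  local = local,
                  local_size = if (local) nrow(X) else NA_integer_,
                  steps = training$steps, seed = training$seed))
}

# pick the PLS component count minimising 5-fold cross-validated
# prediction error of (p_n, p_r) on the training ensemble
cv_pls_components <- function(X, Y, max_components = 8, folds = 5) {
  n <- nrow(X)
  fold <- rep_len(seq_len(folds), n)[sample.int(n)]
  err <- matrix(0, folds, max_components)
  for (f in seq_len(folds)) {
    hold <- fold == f
    fit <- mixOmics::pls(X[!hold, , drop = FALSE], Y[!hold, , drop = FALSE],
                         ncomp = max_components, mode = "regression")
    pred <- predict(fit, X[hold, , drop = FALSE])$predict
    for (k in seq_len(max_components)) {
      err[f, k] <- mean((pred[, , k] - Y[hold, ])^2)
    }
  }
  which.min(colMeans(err))
}

#' Fit (p_n, p_r) by inverting the stationarity approximations
#'
#' Solves the two-equation system equating the analytic stationary mean
#' degree and mean local clustering to the observed values, assuming
#' `p_b = 1` (configurable). The degree balance is inverted exactly for
#' `p_n` as a function of `p_r`, reducing the problem to a
#' one-dimensional root search in `p_r` on the clustering balance; a
#' sign-change scan provides brackets, and the root with the smallest
#' clustering residual wins. Estimates are clipped to \[0, 1\].
#'
#' Recovery on simulated networks is accurate except at high `p_n` with
#' moderately high `p_r` (underestimates, especially `p_r`) and at low
#' `p_n` with very low `p_r` (overestimates `p_r`).
#'
#' @param net either a network (anything [as_social_graph()] accepts),
#'   in which case its mean degree and mean local clustering are used,
#'   or the observed mean degree as a number.
#' @param mean_clustering observed mean local clustering; required when
#'   `net` is a number.
#' @param n network size; required when `net` is a number.
#' @param p_b assumed mother-bond probability.
#' @param tol acceptable residual on the clustering equation.
#' @inheritParams clustering_coefficients
#' @return A `si_fit` object; `tidy()` and `glance()` methods apply.
#' @examples
#' d <- expected_mean_degree(100, p_n = 0.7, p_r = 0.02)
#' c <- expected_mean_clustering(100, p_n = 0.7, p_r = 0.02)
#' fit_analytical(d, c, n = 100) # recovers (0.7, 0.02)
#' @export
fit_analytical <- function(net, mean_clustering = NULL, n = NULL, p_b = 1,
                           tol = 1e-6, isolates = c("zero", "exclude")) {
  isolates <- match.arg(isolates)
  if (is.numeric(net) && length(net) == 1) {
    mean_deg <- net
    if (is.null(mean_clustering) || is.null(n)) {
      abort("supply `mean_clustering` and `n` when fitting summary statistics")
    }
  } else {
    g <- as_social_graph(net)
    n <- igraph::vcount(g)
    mean_deg <- mean(igraph::degree(g))
    mean_clustering <- clustering_coefficients(g, isolates = isolates)$mean_local
  }
  if (mean_deg <= 0 || mean_deg >= n - 1) {
    abort("mean degree must lie strictly between 0 and n - 1")
  }
  if (mean_clustering < 0 || mean_clustering > 1) {
    abort("mean clustering must lie in [0, 1]")
  }

  # degree balance inverted for p_n given p_r
  pn_of_pr <- function(p_r) {
    p_r + (n - 1) / ((n - 2) * mean_deg) *
      (mean_deg - p_b - p_r * (n - 2))
  }
  resid <- function(p_r) {
    p_n <- pn_of_pr(p_r)
    suppressWarnings(
      expected_mean_clustering(n, p_n = p_n, p_r = p_r, p_b = p_b)
    ) - mean_clustering
  }
  # feasible p_r range keeping both probabilities in [0, 1]
  grid <- seq(0, 1, length.out = 201)
  feas <- grid[vapply(grid, function(p) {
    pn <- pn_of_pr(p); pn >= 0 && pn <= 1
  }, logical(1))]
  if (!length(feas)) {
    abort("no (p_n, p_r) in the unit square reproduces the observed mean degree")
  }
  vals <- vapply(feas, function(p) tryCatch(resid(p), error = function(e) NA_real_),
                 numeric(1))
  ok <- !is.na(vals)
  feas <- feas[ok]; vals <- vals[ok]
  roots <- c()
  for (i in seq_len(length(feas) - 1)) {
    if (sign(vals[i]) != sign(vals[i + 1])) {
      rt <- tryCatch(
        uniroot(resid, c(feas[i], feas[i + 1]), tol = 1e-10)$root,
        error = function(e) NA_real_)
      if (!is.na(rt)) roots <- c(roots, rt)
    }
  }
  if (!length(roots)) {
    # no sign change: take the feasible minimiser of |residual|
    best <- feas[which.min(abs(vals))]
    opt <- optimize(function(p) abs(resid(p)),
                    c(max(min(feas), best - 0.01), min(max(feas), best + 0.01)))
    roots <- opt$minimum
  }
  res <- abs(vapply(roots, resid, numeric(1)))
  p_r_hat <- roots[which.min(res)]
  best_res <- min(res)
  if (best_res > tol) {
    abort(sprintf("no solution: smallest clustering residual %.3g exceeds tol %.3g",
                  best_res, tol))
  }
  p_n_raw <- pn_of_pr(p_r_hat)
  clipped <- p_n_raw < 0 || p_n_raw > 1 || p_r_hat < 0 || p_r_hat > 1
  new_si_fit(min(max(p_n_raw, 0), 1), min(max(p_r_hat, 0), 1), "analytical",
             clipped,
             list(mean_degree = mean_deg, mean_clustering = mean_clustering,
                  n = n, p_b = p_b, residual = best_res, isolates = isolates))
}

#' Parameter-recovery validation
#'
#' Draws true `(p_n, p_r)` pairs (uniform on \[0, 0.95\] x \[0, 0.2\] by
#' default), simulates one network per pair, fits it with the chosen
#' method, and reports truth and estimate side by side.
#'
#' @inheritParams simulate_network
#' @param method fitting method to validate.
#' @param truth optional tibble with columns `p_n`, `p_r`; when absent,
#'   `n_draws` pairs are drawn uniformly.
#' @param n_draws number of random truth pairs when `truth` is absent.
#' @param training prebuilt [build_pls_training()] ensemble (PLS method
#'   only); built once internally when absent.
#' @param n_sims training simulations when building the PLS ensemble.
#' @return A tibble of class `si_recovery`: `p_n`, `p_r`, `p_n_hat`,
#'   `p_r_hat`, `method`, `failed`.
#' @export
validate_recovery <- function(method = c("analytical", "pls"), truth = NULL,
                              n_draws = 50, n = 100, steps = 2000, p_b = 1,
                              seed = NULL, training = NULL, n_sims = 500) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) {
    truth <- tibble::tibble(p_n = runif(n_draws, 0, 0.95),
                            p_r = runif(n_draws, 0, 0.2))
  }
  if (method == "pls" && is.null(training)) {
    training <- build_pls_training(n, n_sims = n_sims, steps = steps)
  }
  rows <- purrr::pmap(truth, function(p_n, p_r, ...) {
    net <- simulate_network(n = n, p_n = p_n, p_r = p_r, p_b = p_b,
                            steps = steps)
    fit <- tryCatch({
      if (method == "analytical") fit_analytical(net, p_b = p_b, tol = 0.05)
      else fit_pls(net, training = training)
    }, error = function(e) NULL)
    tibble::tibble(p_n = p_n, p_r = p_r,
                   p_n_hat = if (is.null(fit)) NA_real_ else fit$p_n_hat,
                   p_r_hat = if (is.null(fit)) NA_real_ else fit$p_r_hat,
                   failed = is.null(fit))
  })
  out <- dplyr::bind_rows(rows)
  out$method <- method
  class(out) <- c("si_recovery", class(out))
  out
}

#' Summarise a recovery run
#'
#' @param recovery a tibble from [validate_recovery()].
#' @return A tibble with bias and RMSE per parameter.
#' @export
recovery_summary <- function(recovery) {
  ok <- !recovery$failed
  tibble::tibble(
    parameter = c("p_n", "p_r"),
    bias = c(mean(recovery$p_n_hat[ok] - recovery$p_n[ok]),
             mean(recovery$p_r_hat[ok] - recovery$p_r[ok])),
    rmse = c(sqrt(mean((recovery$p_n_hat[ok] - recovery$p_n[ok])^2)),
             sqrt(mean((recovery$p_r_hat[ok] - recovery$p_r[ok])^2))),
    n_ok = sum(ok), n_failed = sum(!ok)
  )
}
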