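#' Expected stationary mean degree
#'
#' Closed-form solution of the stationarity balance for the mean degree
#' of the social-inheritance model. A random death removes `dbar` bonds
#' on average and leaves the survivors with mean degree
#' `dbar' = dbar (N - 2) / (N - 1)`; the newborn adds
#' `p_b + p_n dbar' + p_r (N - 2 - dbar')` bonds in expectation. Equating
#' losses and gains gives
#' \deqn{\bar d = \frac{p_b + p_r (N - 2)}{1 - (p_n - p_r)\frac{N-2}{N-1}}.}
#'
#' @inheritParams model_params
#' @return The expected stationary mean degree, a single number.
#' @examples
#' expected_mean_degree(100, p_n = 0.8, p_r = 0.01)
#' @export
expected_mean_degree <- function(n, p_n, p_r, p_b = 1) {
  n <- check_count(n, "n", min = 3L)
  check_prob(p_b, "p_b"); check_prob(p_n, "p_n"); check_prob(p_r, "p_r")
  denom <- 1 - (p_n - p_r) * (n - 2) / (n - 1)
  if (denom <= 0) {
    abort("no stationary mean degree: (p_n - p_r) (n-2)/(n-1) must be < 1")
  }
  (p_b + p_r * (n - 2)) / denom
}

# intermediate terms of the clustering balance at a candidate mean
# clustering cc, treating the mother as a typical post-death individual
# (degree d_p = dbar', clustering cc)
clustering_terms <- function(n, p_n, p_r, p_b, cc) {
  dbar <- expected_mean_degree(n, p_n, p_r, p_b)
  dpost <- dbar * (n - 2) / (n - 1)
  d_p <- dpost
  pc_pc <- cc * (d_p - 1)                    # contact's bonds to other contacts
  pc_npc <- max(dpost - 1 - pc_pc, 0)        # contact's bonds to non-contacts
  rho <- min(max(pc_npc / (n - d_p - 2), 0), 1)
  npc_pc <- d_p * rho                        # non-contact's bonds to contacts
  eta <- min(max((dpost - npc_pc) / (n - d_p - 3), 0), 1)
  list(
    dbar = dbar, dpost = dpost, d_p = d_p, rho = rho, eta = eta,
    # closed triangles the newborn creates at the mother, at one of her
    # contacts, and at a non-contact, given that vertex bonds the newborn
    c_t_P = p_n * d_p,
    c_t_PC = p_b + p_n * pc_pc + p_r * pc_npc,
    c_t_NPC = p_n * npc_pc + p_r * (dpost - npc_pc)
  )
}

# net stationarity residual at candidate mean clustering cc: clustering
# added by a birth minus the cc lost with a random death
clustering_balance <- function(cc, n, p_n, p_r, p_b) {
  tm <- clustering_terms(n, p_n, p_r, p_b, cc)
  shift <- function(d, c, ct) (c * choose(d, 2) + ct) / choose(d + 1, 2) - c
  delta_existing <-
    p_b * shift(tm$d_p, cc, tm$c_t_P) +
    tm$d_p * p_n * shift(tm$dpost, cc, tm$c_t_PC) +
    (n - tm$d_p - 2) * p_r * shift(tm$dpost, cc, tm$c_t_NPC)
  c_nb <- newborn_clustering_moments(n, p_b, p_n, p_r, tm$d_p, cc,
                                     tm$rho, tm$eta)
  delta_existing + c_nb - cc
}

#' Expected stationary mean local clustering coefficient
#'
#' Solves the stationarity condition that the mean local clustering lost
#' with a random death equals the clustering added by a birth: the birth
#' changes the coefficients of the individuals the newborn bonds
#' (mother, her contacts, and non-contacts, each receiving the expected
#' closed triangles the newborn creates there) and contributes the
#' newborn's own coefficient, whose ratio of closed to total pairs is
#' approximated by its second-order moments. The mother is treated as a
#' typical individual of the post-death network. The resulting scalar
#' equation is solved for the clustering coefficient on \[0, 1\].
#'
#' The approximation is known to break down for low `p_n` combined with
#' very low `p_r`, where it underestimates the simulated clustering; a
#' solution outside \[0, 1\] is clamped with a warning.
#'
#' @inheritParams model_params
#' @param tol root-finding tolerance.
#' @return The expected stationary mean local clustering coefficient.
#' @examples
#' expected_mean_clustering(100, p_n = 0.9, p_r = 0.1)
#' @export
expected_mean_clustering <- function(n, p_n, p_r, p_b = 1, tol = 1e-10) {
  n <- check_count(n, "n", min = 4L)
  check_prob(p_b, "p_b"); check_prob(p_n, "p_n"); check_prob(p_r, "p_r")
  f <- function(cc) clustering_balance(cc, n, p_n, p_r, p_b)
  f0 <- f(0); f1 <- f(1)
  if (abs(f0) < tol) return(0)
  if (abs(f1) < tol) return(1)
  if (sign(f0) != sign(f1)) {
    return(uniroot(f, c(0, 1), f.lower = f0, f.upper = f1, tol = tol)$root)
  }
  # no sign change on [0, 1]: minimise |residual| and flag the breakdown
  opt <- optimize(function(cc) abs(f(cc)), c(0, 1))
  warn(sprintf(paste0("clustering balance has no root in [0, 1] ",
                      "(best residual %.3g); returning the minimiser -- ",
                      "approximation breakdown region"), opt$objective))
  opt$minimum
}

#' Stationarity approximations bundle
#'
#' Computes the analytic stationary mean degree, post-death mean degree
#' and mean local clustering coefficient together with the residual of
#' the clustering balance at the solution.
#'
#' @inheritParams expected_mean_clustering
#' @return An object of class `si_approx`.
#' @examples
#' glance(stationary_approx(100, p_n = 0.9, p_r = 0.1))
#' @export
stationary_approx <- function(n, p_n, p_r, p_b = 1, tol = 1e-10) {
  dbar <- expected_mean_degree(n, p_n, p_r, p_b)
  cbar <- expected_mean_clustering(n, p_n, p_r, p_b, tol = tol)
  structure(list(
    mean_degree = dbar,
    mean_clustering = cbar,
    post_death_degree = dbar * (n - 2) / (n - 1),
    residual = clustering_balance(cbar, n, p_n, p_r, p_b),
    params = list(n = n, p_b = p_b, p_n = p_n, p_r = p_r)
  ), class = "si_approx")
}

#' @export
print.si_approx <- function(x, ...) {
  cat(sprintf("<si_approx> n=%d p_b=%g p_n=%g p_r=%g\n", x$params$n,
              x$params$p_b, x$params$p_n, x$params$p_r))
  cat(sprintf("  mean degree     %.4f\n", x$mean_degree))
  cat(sprintf("  mean clustering %.4f (balance residual %.2g)\n",
              x$mean_clustering, x$residual))
  invisible(x)
}

#' @rdname stationary_approx
#' @param x a `si_approx` object.
#' @param ... unused.
#' @export
glance.si_approx <- function(x, ...) {
  tibble::tibble(
    n = x$params$n, p_b = x$params$p_b, p_n = x$params$p_n, p_r = x$params$p_r,
    mean_degree = x$mean_degree, mean_clustering = x$mean_clustering,
    post_death_degree = x$post_death_degree, residual = x$residual
  )
}

# birth kernel: B[l + 1, d + 1] = P(newborn degree = d | mother degree l),
# the convolution of Bernoulli(p_b), Binomial(l, p_n), Binomial(n-2-l, p_r)
birth_kernel <- function(n, p_n, p_r, p_b = 1) {
  B <- matrix(0, n, n)
  for (l in 0:(n - 1)) {
    pn_part <- dbinom(0:l, l, p_n)
    m <- n - 2 - l
    pr_part <- if (m >= 0) dbinom(0:m, m, p_r) else 1
    conv <- convolve_pmf(pn_part, pr_part)
    full <- (1 - p_b) * c(conv, 0) + p_b * c(0, conv)
    length(full) <- n
    full[is.na(full)] <- 0
    B[l + 1, ] <- full
  }
  B
}

convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

#' Mean-field stationary degree distribution
#'
#' Solves the mean-field rate equation for the degree distribution
#' `phi_d` (`d = 0..n-1`) of the social-inheritance model. Per
#' birth--death event a focal individual of degree `d` gains a bond when
#' the dying individual is not itself or a neighbour (probability
#' `(n-1-d)/n`) and the newborn bonds it, the latter obtained by
#' conditioning on the newborn's mother being the focal individual
#' (probability `1/(n-1)`, bond with `p_b`), one of its neighbours
#' (`d/(n-1)`, bond with `p_n`) or neither (bond with `p_r`). It loses a
#' bond when a neighbour dies (`d/n`) and the newborn does not bond it.
#' Individuals of degree `d` are themselves replaced at rate `1/n` by
#' newborns whose degree follows the birth distribution `b_d`, the
#' mixture over mothers drawn from the post-death distribution of
#' `p_b`-mother-link plus binomial inherited and random bonds. The
#' stationary distribution is found by damped fixed-point iteration of
#' the per-event map, started from the binomial distribution with the
#' analytic stationary mean.
#'
#' @inheritParams model_params
#' @param tol convergence threshold on the total-variation change per
#'   iteration.
#' @param max_iter iteration cap.
#' @param damping step fraction of the fixed-point map applied per
#'   iteration.
#' @return An object of class `si_meanfield`: a list with the
#'   distribution tibble (`d`, `phi`, `birth`, `post_death`), the
#'   per-degree gain and loss probabilities, the iteration count and the
#'   final total-variation change.
#' @examples
#' mf <- stationary_degree_distribution(50, p_n = 0.8, p_r = 0.01)
#' sum(mf$distribution$phi * mf$distribution$d) # close to the analytic mean
#' @export
stationary_degree_distribution <- function(n, p_n, p_r, p_b = 1,
                                           tol = 1e-10, max_iter = 200000,
                                           damping = 0.5) {
  n <- check_count(n, "n", min = 3L)
  check_prob(p_b, "p_b"); check_prob(p_n, "p_n"); check_prob(p_r, "p_r")
  d <- 0:(n - 1)
  w <- function(deg) (p_b + p_n * deg + p_r * (n - 2 - deg)) / (n - 1)
  gain <- (n - 1 - d) / n * w(d)
  loss <- d / n * (1 - w(pmax(d - 1, 0)))
  loss[1] <- 0
  B <- birth_kernel(n, p_n, p_r, p_b)

  dbar <- expected_mean_degree(n, p_n, p_r, p_b)
  phi <- dbinom(d, n - 1, min(dbar / (n - 1), 1))
  phi <- phi / sum(phi)

  iter <- 0L
  tv <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    post <- phi * (1 - d / n) + c(phi[-1] * (d[-1] / n), 0)
    b <- as.vector(crossprod(B, post))
    flow_in <- c(0, gain[-n] * phi[-n]) + c(loss[-1] * phi[-1], 0)
    delta <- (b - phi) / n + flow_in - (gain + loss) * phi
    phi_new <- phi + damping * delta
    phi_new[phi_new < 0] <- 0
    phi_new <- phi_new / sum(phi_new)
    tv <- 0.5 * sum(abs(phi_new - phi))
    phi <- phi_new
    if (tv < tol) break
  }
  if (tv >= tol) {
    abort(sprintf("mean-field iteration did not converge (last TV change %.3g)", tv))
  }
  post <- phi * (1 - d / n) + c(phi[-1] * (d[-1] / n), 0)
  structure(list(
    distribution = tibble::tibble(d = d, phi = phi,
                                  birth = as.vector(crossprod(B, post)),
                                  post_death = post),
    gain_prob = gain, loss_prob = loss,
    iterations = iter, tv_change = tv,
    params = list(n = n, p_b = p_b, p_n = p_n, p_r = p_r)
  ), class = "si_meanfield")
}

#' @export
print.si_meanfield <- function(x, ...) {
  cat(sprintf("<si_meanfield> n=%d p_b=%g p_n=%g p_r=%g\n", x$params$n,
              x$params$p_b, x$params$p_n, x$params$p_r))
  cat(sprintf("  mean degree %.4f | converged in %d iterations (TV %.2g)\n",
              sum(x$distribution$d * x$distribution$phi), x$iterations,
              x$tv_change))
  invisible(x)
}

#' @rdname stationary_degree_distribution
#' @param x a `si_meanfield` object.
#' @param ... unused.
#' @export
tidy.si_meanfield <- function(x, ...) x$distribution
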