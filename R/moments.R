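# Exact low-order moments of the newborn's triangle counts.
#
# The newborn's bonds split into three independent classes: the mother
# (Bernoulli(p_b)), the mother's contacts (Binomial(d_p, p_n)) and the
# remaining survivors (Binomial(N - d_p - 2, p_r)). Its local clustering
# is the ratio T_c / T_t of closed to total pairs among those bonds; the
# stationarity solver needs E[T_c], E[T_t], Var(T_t) and Cov(T_c, T_t).
# Both counts are quadratic polynomials in the class totals, so all four
# quantities reduce to mixed raw moments of order <= 4, which factorise
# over the independent classes. Binomial raw moments extend to
# non-integer size via factorial moments, which matters because the
# typical mother degree d_p is a real number.

raw_moments_binomial <- function(size, prob) {
  f1 <- size * prob
  f2 <- size * (size - 1) * prob^2
  f3 <- size * (size - 1) * (size - 2) * prob^3
  f4 <- size * (size - 1) * (size - 2) * (size - 3) * prob^4
  c(1, f1, f2 + f1, f3 + 3 * f2 + f1, f4 + 6 * f3 + 7 * f2 + f1)
}

raw_moments_bernoulli <- function(prob) c(1, rep(prob, 4))

# polynomials in three variables, as matrices [i, j, k, coef]
poly_mul <- function(p, q) {
  idx <- expand.grid(r = seq_len(nrow(p)), s = seq_len(nrow(q)))
  m <- cbind(p[idx$r, 1] + q[idx$s, 1],
             p[idx$r, 2] + q[idx$s, 2],
             p[idx$r, 3] + q[idx$s, 3],
             p[idx$r, 4] * q[idx$s, 4])
  key <- paste(m[, 1], m[, 2], m[, 3])
  coefs <- rowsum(m[, 4], key)
  parts <- do.call(rbind, strsplit(rownames(coefs), " "))
  cbind(as.numeric(parts[, 1]), as.numeric(parts[, 2]),
        as.numeric(parts[, 3]), as.numeric(coefs))
}

poly_expect <- function(p, ma, mb, mc) {
  sum(p[, 4] * ma[p[, 1] + 1] * mb[p[, 2] + 1] * mc[p[, 3] + 1])
}

# E[T_c / T_t] by a second-order expansion of the ratio of moments:
#   E[X]/E[Y] - Cov(X, Y)/E[Y]^2 + E[X] Var(Y)/E[Y]^3
# cp: density among the mother's contacts; rho: contact / non-contact
# edge density; eta: density among non-contacts. Returns 0 when the
# newborn is expected to have fewer than two bonds (no pair to close).
newborn_clustering_moments <- function(n, p_b, p_n, p_r, d_p, cp, rho, eta) {
  ma <- raw_moments_bernoulli(p_b)
  mb <- raw_moments_binomial(d_p, p_n)
  mc <- raw_moments_binomial(n - d_p - 2, p_r)
  s <- rbind(c(1, 0, 0, 1), c(0, 1, 0, 1), c(0, 0, 1, 1))
  s2 <- poly_mul(s, s)
  tt <- rbind(cbind(s2[, 1:3, drop = FALSE], s2[, 4] / 2),
              cbind(s[, 1:3, drop = FALSE], -s[, 4] / 2))
  tc <- rbind(c(1, 1, 0, 1),
              c(0, 2, 0, cp / 2), c(0, 1, 0, -cp / 2),
              c(0, 1, 1, rho),
              c(0, 0, 2, eta / 2), c(0, 0, 1, -eta / 2))
  e_tt <- poly_expect(tt, ma, mb, mc)
  if (e_tt < 1e-12) return(0)
  e_tc <- poly_expect(tc, ma, mb, mc)
  e_tt2 <- poly_expect(poly_mul(tt, tt), ma, mb, mc)
  e_tctt <- poly_expect(poly_mul(tc, tt), ma, mb, mc)
  var_tt <- e_tt2 - e_tt^2
  cov_tctt <- e_tctt - e_tc * e_tt
  e_tc / e_tt - cov_tctt / e_tt^2 + e_tc * var_tt / e_tt^3
}
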