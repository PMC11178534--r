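# Shared fixtures: small model eyes and brute-force oracles.

small_model <- function(n = 96) eye_model(image_size = c(n, n))

# exhaustive-enumeration oracle for the Wilcoxon signed-rank p-value:
# all 2^n sign assignments of the ranked |differences|
enum_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  switch(alternative,
         greater = mean(vs >= v_obs),
         less = mean(vs <= v_obs),
         two.sided = min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs))))
}

# exhaustive-enumeration oracle for the two-sided Mann-Whitney p-value:
# all C(nx+ny, nx) assignments of the pooled ranks to the first sample
enum_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# ordinary least squares on the piecewise-time design, the closed-form
# reference for the mixed model when variance components vanish
ols_piecewise_slopes <- function(cohort, response = "response") {
  d <- cohort
  d$t1 <- pmin(d$visit_time, 1)
  d$t2 <- pmax(d$visit_time - 1, 0)
  unname(coef(lm(reformulate(c("t1", "t2"), response = response), d))[c("t1", "t2")])
}
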