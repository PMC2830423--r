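## build a delta_profile object directly from a matrix (positions x 20)
as_profile <- function(delta, se = delta * 0 + 0.01) {
  dimnames(delta) <- list(position = seq_len(nrow(delta)), aa = AMINO_ACIDS)
  dimnames(se) <- dimnames(delta)
  structure(list(delta = delta, se = se, variant = "rate_difference",
                 positions = seq_len(nrow(delta))), class = "delta_profile")
}

test_that("rmsd_matrix matches closed forms and hand arithmetic", {
  d <- as_profile(matrix(stats::rnorm(3 * 20, sd = 0.02), 3))
  m <- rmsd_matrix(d, d)
  expect_equal(unname(diag(unclass(m))), rep(0, 3))

  ## +0.1 in exactly one amino acid -> 0.1/sqrt(20)
  a <- matrix(0, 1, 20); b <- a; b[1, 5] <- 0.1
  m2 <- rmsd_matrix(as_profile(a), as_profile(b))
  expect_equal(m2[1, 1], 0.1 / sqrt(20))

  ## 2x2 toy against direct elementwise computation
  A <- matrix(stats::rnorm(2 * 20, sd = 0.05), 2)
  B <- matrix(stats::rnorm(2 * 20, sd = 0.05), 2)
  m3 <- rmsd_matrix(as_profile(A), as_profile(B))
  for (i in 1:2) for (j in 1:2)
    expect_equal(m3[i, j], sqrt(mean((A[i, ] - B[j, ])^2)))

  ## symmetry under swapping the profiles = transposition
  expect_equal(unclass(rmsd_matrix(as_profile(B), as_profile(A))),
               t(unclass(m3)), ignore_attr = TRUE)
})

test_that("background equals raw when permutation cannot change anything", {
  ## identical usage vectors for all proteins -> permutation invariant
  rs <- ruleset(c("P1", "P2", "P3"))
  U <- matrix(3L, 3, 20, dimnames = list(rs$proteins, AMINO_ACIDS))
  D <- matrix(2L, 3, 20, dimnames = list(rs$proteins, AMINO_ACIDS))
  D[, "G"] <- 7L
  tab <- usage_table(U, D)
  reo <- reo_matrix(rs)
  raw <- rmsd_matrix(delta_profile(reo, tab), delta_profile(reo, tab))
  bg <- background_matrix(tab, tab, reo, reo, reps = 5, seed = 1)
  expect_equal(unclass(bg), unclass(raw), ignore_attr = TRUE)

  ## single-protein subunits: permutation vacuous, background = raw
  rs1 <- ruleset("P1")
  t1 <- toy_usage("P1")
  r1 <- reo_matrix(rs1)
  raw1 <- rmsd_matrix(delta_profile(r1, t1), delta_profile(r1, t1))
  expect_warning(bg1 <- background_matrix(t1, t1, r1, r1, reps = 3, seed = 1),
                 "vacuous")
  expect_equal(unclass(bg1), unclass(raw1), ignore_attr = TRUE)
})

test_that("background converges to the exhaustive permutation average", {
  rs <- ruleset(c("P1", "P2", "P3"))
  tL <- toy_usage(rs$proteins, seed = 21)
  tS <- toy_usage(rs$proteins, seed = 22)
  reo <- reo_matrix(rs)

  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  apply_perm <- function(tab, p) {
    tab$U <- tab$U[p, , drop = FALSE]; rownames(tab$U) <- tab$proteins
    tab$D <- tab$D[p, , drop = FALSE]; rownames(tab$D) <- tab$proteins
    tab$U_total <- stats::setNames(tab$U_total[p], tab$proteins)
    tab$D_total <- stats::setNames(tab$D_total[p], tab$proteins)
    tab
  }
  acc <- 0; vals <- list()
  for (a in 1:6) for (b in 1:6) {
    m <- unclass(rmsd_matrix(
      delta_profile(reo, apply_perm(tL, perms[a, ])),
      delta_profile(reo, apply_perm(tS, perms[b, ]))))
    acc <- acc + m
    vals[[length(vals) + 1]] <- m
  }
  exact <- acc / 36

  reps <- 4000
  bg <- background_matrix(tL, tS, reo, reo, reps = reps, seed = 9)
  ## per-entry Monte-Carlo tolerance: 4 sigma of the mean over the 36-point
  ## permutation distribution
  sds <- apply(simplify2array(vals), c(1, 2), stats::sd)
  tol <- 4 * sds / sqrt(reps)
  expect_true(all(abs(unclass(bg) - exact) <= tol + 1e-12))
})

test_that("background is invariant under protein relabelling", {
  rs <- ruleset(c("P1", "P2", "P3"))
  tL <- toy_usage(rs$proteins, seed = 31)
  tS <- toy_usage(rs$proteins, seed = 32)
  reo <- reo_matrix(rs)
  bg1 <- background_matrix(tL, tS, reo, reo, reps = 2000, seed = 5)

  ## relabel proteins of the LSU-side inputs consistently
  relab <- c(P1 = "Q2", P2 = "Q3", P3 = "Q1")
  rs2 <- ruleset(unname(relab[rs$proteins]))
  tL2 <- tL
  tL2$proteins <- unname(relab[tL$proteins])
  rownames(tL2$U) <- rownames(tL2$D) <- tL2$proteins
  names(tL2$U_total) <- names(tL2$D_total) <- tL2$proteins
  reo2 <- reo_matrix(rs2)
  bg2 <- background_matrix(tL2, tS, reo2, reo, reps = 2000, seed = 5)
  ## same seed, same structure: identical up to the (identical) sampling
  expect_equal(unclass(bg2), unclass(bg1), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("residual_matrix subtracts elementwise with dimension checks", {
  raw <- structure(matrix(1:6 / 10, 2, 3), class = c("rmsd_matrix", "matrix"),
                   kind = "raw")
  bg0 <- structure(matrix(0, 2, 3), class = c("rmsd_matrix", "matrix"),
                   kind = "background")
  expect_equal(unclass(residual_matrix(raw, raw)), matrix(0, 2, 3),
               ignore_attr = TRUE)
  expect_equal(unclass(residual_matrix(raw, bg0)), unclass(raw),
               ignore_attr = TRUE)
  expect_error(residual_matrix(raw, structure(matrix(0, 3, 2),
                                              class = "rmsd_matrix")),
               "dimension")
})

test_that("structure_test recovers closed-form Z scores", {
  ## 1x2 replicate matrices with hand-chosen entries
  reps <- list(matrix(c(0, 0), 1), matrix(c(1, 3), 1), matrix(c(2, 6), 1))
  ms <- sapply(reps, mean)            # 0, 2, 4
  vs <- sapply(reps, function(m) stats::var(as.vector(m)))
  ## actual with mean = mean + 3 sd and variance = mean + 3 sd of the nulls
  target_mean <- mean(ms) + 3 * stats::sd(ms)
  target_var <- mean(vs) + 3 * stats::sd(vs)
  delta <- sqrt(2 * target_var)
  actual <- matrix(c(target_mean - delta / 2, target_mean + delta / 2), 1)
  st <- structure_test(actual, reps)
  expect_equal(st$z_mean, 3)
  expect_equal(st$z_var, 3)
  expect_equal(st$p_mean, stats::pnorm(3, lower.tail = FALSE))
  expect_equal(st$p_var, 1 - stats::pnorm(3), tolerance = 1e-12)

  expect_error(structure_test(actual, reps[1]), "at least 2")
  expect_error(structure_test(actual, list(matrix(0, 1, 2), matrix(0, 1, 2))),
               "degenerate")
})

test_that("rank-based permutation p-values are uniform under the null", {
  ## validates the exchangeability of the actual data with its
  ## randomisations when there is no code drift
  ps <- vapply(1:150, function(s) {
    w <- simulate_world(n_proteins = c(10, 10), drift = 0,
                        sites = c(U = 50, D = 50), seed = 2000 + s)
    reoL <- reo_matrix(w$lsu$rules); reoS <- reo_matrix(w$ssu$rules)
    dL <- delta_profile(reoL, w$lsu$usage)
    dS <- delta_profile(reoS, w$ssu$usage)
    raw <- rmsd_matrix(dL, dS)
    bg <- background_matrix(w$lsu$usage, w$ssu$usage, reoL, reoS,
                            reps = 60, seed = s * 3 + 1)
    rr <- residual_matrix(raw, bg)
    nulls <- randomized_residuals(w$lsu$usage, w$ssu$usage, reoL, reoS, bg,
                                  reps = 60, seed = s * 3 + 2)
    structure_test(rr, nulls)$p_var_emp
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("structured synthetic data is detected against its randomisations", {
  hits <- 0
  for (s in 1:10) {
    w <- simulate_world(seed = s + 400)
    reoL <- reo_matrix(w$lsu$rules); reoS <- reo_matrix(w$ssu$rules)
    dL <- delta_profile(reoL, w$lsu$usage)
    dS <- delta_profile(reoS, w$ssu$usage)
    raw <- rmsd_matrix(dL, dS)
    bg <- background_matrix(w$lsu$usage, w$ssu$usage, reoL, reoS,
                            reps = 80, seed = s)
    rr <- residual_matrix(raw, bg)
    nulls <- randomized_residuals(w$lsu$usage, w$ssu$usage, reoL, reoS, bg,
                                  reps = 60, seed = s + 1)
    if (structure_test(rr, nulls)$p_var < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
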