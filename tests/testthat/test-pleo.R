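fork <- parse_ruleset(c("A:", "B: A", "C: A"))

test_that("count_pleos handles the canonical small cases", {
  free4 <- ruleset(c("A", "B", "C", "D"))
  expect_equal(count_pleos(free4), 24)
  chain5 <- parse_ruleset(c("A:", "B: A", "C: B", "D: C", "E: D"))
  expect_equal(count_pleos(chain5), 1)
  expect_equal(count_pleos(fork), 2)
  expect_equal(count_pleos(fork, method = "enumerate"), 2)
  expect_error(count_pleos(ruleset(paste0("P", 1:30)), limit = 24),
               "limit")
})

test_that("enumeration is exact, complete and lexicographic", {
  anti <- ruleset(c("A", "B"))
  expect_equal(enumerate_pleos(anti),
               matrix(c("A", "B", "B", "A"), 2, 2, byrow = TRUE,
                      dimnames = list(NULL, c("pos1", "pos2"))))
  chain <- parse_ruleset(c("A:", "B: A", "C: B"))
  expect_equal(unname(enumerate_pleos(chain)),
               matrix(c("A", "B", "C"), 1))
  expect_equal(unname(enumerate_pleos(fork)),
               matrix(c("A", "B", "C",
                        "A", "C", "B"), 2, 3, byrow = TRUE))
  expect_error(enumerate_pleos(ruleset(LETTERS[1:10]), cap = 100), "cap")
})

test_that("sampling respects constraints and the uniform law", {
  chain <- parse_ruleset(c("A:", "B: A", "C: B"))
  s <- sample_pleos(chain, 50, seed = 1)
  expect_true(all(s[, 1] == "A" & s[, 2] == "B" & s[, 3] == "C"))

  anti <- ruleset(c("A", "B"))
  s <- sample_pleos(anti, 1e4, seed = 2)
  expect_lt(abs(mean(s[, 1] == "A") - 0.5), 0.02)

  ## identical seed => identical sample; different methods differ in law only
  expect_identical(sample_pleos(fork, 20, seed = 3),
                   sample_pleos(fork, 20, seed = 3))

  ## every sampled order respects all prerequisites (both methods)
  set.seed(4)
  rs <- random_ruleset(7, 0.35)
  E <- ruleset_edges(rs)
  for (m in c("uniform", "frontier")) {
    s <- sample_pleos(rs, 500, seed = 5, method = m, labels = FALSE)
    pos <- matrix(0L, nrow(s), ncol(s))
    for (k in seq_len(ncol(s))) pos[cbind(seq_len(nrow(s)), s[, k])] <- k
    for (e in seq_len(nrow(E)))
      expect_true(all(pos[, E[e, 1]] < pos[, E[e, 2]]))
  }
})

test_that("uniform sampler frequencies match exact proportions (chi-square)", {
  set.seed(20)
  rejected <- 0
  for (rep in 1:20) {
    rs <- random_ruleset(5, 0.4)
    orders <- enumerate_pleos(rs)
    k <- nrow(orders)
    if (k == 1) next
    key <- apply(orders, 1, paste, collapse = "")
    s <- sample_pleos(rs, 200 * k, seed = 100 + rep)
    skey <- apply(s, 1, paste, collapse = "")
    countv <- table(factor(skey, levels = key))
    p <- suppressWarnings(stats::chisq.test(countv,
                                            p = rep(1 / k, k))$p.value)
    if (p < 0.01) rejected <- rejected + 1
  }
  expect_lte(rejected, 1)
})

test_that("exact REO matrices match brute force and are doubly stochastic", {
  chain <- parse_ruleset(c("A:", "B: A", "C: B"))
  expect_equal(unclass(reo_matrix(chain)), diag(3), ignore_attr = TRUE)

  anti3 <- ruleset(c("A", "B", "C"))
  expect_true(all(abs(reo_matrix(anti3) - 1 / 3) < 1e-12))

  P <- reo_matrix(fork)
  expect_equal(P["A", 1], 1)
  expect_equal(unname(P["B", 2:3]), c(0.5, 0.5))
  expect_equal(unname(P["C", 2:3]), c(0.5, 0.5))

  set.seed(7)
  for (rep in 1:5) {
    rs <- random_ruleset(6, 0.3)
    P <- reo_matrix(rs)
    expect_true(all(abs(rowSums(P) - 1) < 1e-12))
    expect_true(all(abs(colSums(P) - 1) < 1e-12))
    expect_equal(unclass(P), brute_reo(rs), ignore_attr = TRUE)
  }
})

test_that("compiled REO matrices agree with their orders", {
  orders <- enumerate_pleos(fork)
  P <- reo_matrix(fork, orders)
  expect_equal(unclass(P), unclass(reo_matrix(fork)), ignore_attr = TRUE)
  expect_error(reo_matrix(fork, matrix(c("A", "B"), 1)), "inconsistent")
})

test_that("remove_excluded closes ranks correctly", {
  chain <- parse_ruleset(c("A:", "B: A", "C: B"))
  P <- reo_matrix(chain)
  expect_identical(remove_excluded(P, chain, drop = character()), P)
  P2 <- remove_excluded(P, chain, drop = "B")
  expect_equal(unclass(P2), diag(2), ignore_attr = TRUE)
  expect_equal(rownames(P2), c("A", "C"))

  Pf <- remove_excluded(reo_matrix(fork), fork, drop = "C")
  expect_equal(unclass(Pf), diag(2), ignore_attr = TRUE)

  ## exact conditional DP vs re-tabulated enumeration, random cases
  set.seed(8)
  for (rep in 1:5) {
    rs <- random_ruleset(6, 0.3)
    drop <- sample(rs$proteins, 2)
    exact <- remove_excluded(reo_matrix(rs), rs, drop = drop)
    orders <- enumerate_pleos(rs)
    compiled <- remove_excluded(reo_matrix(rs, orders), rs, drop = drop)
    expect_equal(unclass(exact), unclass(compiled), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_true(all(abs(rowSums(exact) - 1) < 1e-12))
    expect_true(all(abs(colSums(exact) - 1) < 1e-12))
  }
})

test_that("REO TSV round-trips and convergence diagnostic shrinks with n", {
  P <- reo_matrix(lsu_ruleset())
  tf <- tempfile(fileext = ".tsv")
  write_reo_matrix(P, tf)
  P2 <- read_reo_matrix(tf)
  expect_equal(unclass(P2), unclass(P), ignore_attr = TRUE, tolerance = 1e-12)

  rs <- ssu_ruleset()
  small <- sample_pleos(rs, 400, seed = 1)
  large <- sample_pleos(rs, 8000, seed = 1)
  expect_gt(sampling_convergence(rs, small),
            sampling_convergence(rs, large))
})
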