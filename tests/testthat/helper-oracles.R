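## Brute-force oracles, independent of the package's DP/C++ code paths.

## all permutations of 1:n as a matrix (rows = permutations)
all_perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (n == 1) m <- matrix(1L, 1, 1)
    else {
      prev <- all_perms(n - 1)
      m <- do.call(rbind, lapply(seq_len(n), function(k) {
        cbind(k, ifelse(prev >= k, prev + 1L, prev))
      }))
    }
    cache[[key]] <<- m
    m
  }
})

## edges of a ruleset as an integer (from, to) matrix
ruleset_edges <- function(rs) {
  idx <- stats::setNames(seq_along(rs$proteins), rs$proteins)
  out <- matrix(integer(), 0, 2)
  for (p in names(rs$dependencies))
    for (d in rs$dependencies[[p]])
      out <- rbind(out, c(idx[[d]], idx[[p]]))
  out
}

## brute force: filter all n! permutations against the constraints
brute_filter_orders <- function(rs) {
  n <- length(rs$proteins)
  M <- all_perms(n)
  pos <- matrix(0L, nrow(M), n)
  for (k in seq_len(n)) pos[cbind(seq_len(nrow(M)), M[, k])] <- k
  ok <- rep(TRUE, nrow(M))
  E <- ruleset_edges(rs)
  if (nrow(E)) for (e in seq_len(nrow(E)))
    ok <- ok & pos[, E[e, 1]] < pos[, E[e, 2]]
  M[ok, , drop = FALSE]
}

brute_count <- function(rs) nrow(brute_filter_orders(rs))

## brute-force REO frequencies (proteins x positions)
brute_reo <- function(rs) {
  M <- brute_filter_orders(rs)
  n <- length(rs$proteins)
  P <- matrix(0, n, n, dimnames = list(rs$proteins, seq_len(n)))
  for (i in seq_len(n)) P[, i] <- tabulate(M[, i], n) / nrow(M)
  P
}

## random DAG ruleset on n proteins (edges respect the label order)
random_ruleset <- function(n, p_edge = 0.3) {
  prots <- LETTERS[seq_len(n)]
  deps <- stats::setNames(vector("list", n), prots)
  for (k in seq_len(n)) {
    if (k == 1) { deps[[k]] <- character(); next }
    sel <- stats::runif(k - 1) < p_edge
    deps[[k]] <- prots[seq_len(k - 1)][sel]
  }
  ruleset(prots, deps)
}

## small deterministic usage table for toy examples
toy_usage <- function(proteins, seed = 99, n_u = 40, n_d = 40) {
  set.seed(seed)
  U <- t(vapply(proteins, function(p)
    as.vector(stats::rmultinom(1, n_u, rep(1, 20))), numeric(20)))
  D <- t(vapply(proteins, function(p)
    as.vector(stats::rmultinom(1, n_d, rep(1, 20))), numeric(20)))
  dimnames(U) <- dimnames(D) <- list(proteins, AMINO_ACIDS)
  usage_table(U, D)
}
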