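#' Pairwise RMSD matrix between two chronology delta profiles
#'
#' Entry (i_L, i_S) is the root mean square distance over the n = 20 amino
#' acids between the usage-delta vectors of LSU chronology position i_L and
#' SSU position i_S:
#' \deqn{RMSD(i_L, i_S) = \sqrt{\tfrac{1}{20}\sum_A (D_{i_L A} - D_{i_S A})^2}.}
#'
#' @param dL,dS `delta_profile` objects (rows of the result follow `dL`).
#' @return an `rmsd_matrix` of kind `"raw"`.
#' @export
rmsd_matrix <- function(dL, dS) {
  A <- dL$delta
  B <- dS$delta
  if (!identical(colnames(A), colnames(B)))
    stop("profiles cover different amino-acid sets")
  m <- rmsd_cross(A, B)
  dimnames(m) <- list(LSU = seq_len(nrow(A)), SSU = seq_len(nrow(B)))
  structure(m, class = c("rmsd_matrix", "matrix"), kind = "raw")
}

## fast cross-RMSD via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b
rmsd_cross <- function(A, B) {
  n <- ncol(A)
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sq[sq < 0] <- 0
  sqrt(sq / n)
}

#' Background RMSD matrix from usage randomised across proteins
#'
#' The raw RMSD matrix inherits structure from the model itself: adjacent
#' chronology positions share proteins, and terminal positions average fewer
#' proteins and so have larger variance. To remove these artifacts, the
#' per-protein (U, D) count-vector pairs are permuted across proteins within
#' each subunit independently, the delta profiles and RMSD matrix are
#' recomputed, and the entries are averaged over `reps` replicates.
#'
#' @param tL,tS `usage_table`s for the two subunits.
#' @param reoL,reoS `reo_matrix` objects (usage-excluded proteins already
#'   removed).
#' @param reps number of randomisation replicates (default 10000).
#' @param seed optional integer for reproducibility.
#' @param variant delta-profile variant, passed to [delta_profile()].
#' @param paired permute intact (U, D) pairs (default); `FALSE` permutes the
#'   U and D vectors independently.
#' @return an `rmsd_matrix` of kind `"background"` with attribute
#'   `provenance = list(reps, seed, paired)`.
#' @export
background_matrix <- function(tL, tS, reoL, reoS, reps = 10000, seed = NULL,
                              variant = "rate_difference", paired = TRUE) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (length(rownames(reoL)) < 2 || length(rownames(reoS)) < 2)
    warning("fewer than 2 proteins in a subunit; permutation is vacuous")
  acc <- NULL
  for (r in seq_len(reps)) {
    m <- unclass(rmsd_matrix(
      delta_profile(reoL, permute_usage(tL, rownames(reoL), paired), variant),
      delta_profile(reoS, permute_usage(tS, rownames(reoS), paired), variant)))
    acc <- if (is.null(acc)) m else acc + m
  }
  bg <- acc / reps
  structure(bg, class = c("rmsd_matrix", "matrix"), kind = "background",
            provenance = list(reps = reps, seed = seed, paired = paired))
}

## permute usage vectors across the given proteins (others untouched)
permute_usage <- function(tab, proteins, paired = TRUE) {
  i <- match(proteins, tab$proteins)
  p1 <- i[sample.int(length(i))]
  tab$U[i, ] <- tab$U[p1, , drop = FALSE]
  tab$U_total[i] <- tab$U_total[p1]
  p2 <- if (paired) p1 else i[sample.int(length(i))]
  tab$D[i, ] <- tab$D[p2, , drop = FALSE]
  tab$D_total[i] <- tab$D_total[p2]
  tab
}

#' Residual RMSD matrix
#'
#' Elementwise difference raw minus background; the matrix on which the
#' chronological fitting (random-walk alignment) operates.
#'
#' @param raw,background `rmsd_matrix` objects of matching dimension.
#' @return an `rmsd_matrix` of kind `"residual"`.
#' @export
residual_matrix <- function(raw, background) {
  if (!all(dim(raw) == dim(background))) stop("dimension mismatch")
  structure(unclass(raw) - unclass(background),
            class = c("rmsd_matrix", "matrix"), kind = "residual")
}

#' Residual matrices of randomised replicates
#'
#' Generates fresh randomisations of the usage tables, computes each
#' replicate's raw RMSD matrix, and subtracts the supplied background,
#' giving the null distribution of residual matrices used by
#' [structure_test()].
#'
#' @inheritParams background_matrix
#' @param background an `rmsd_matrix` of kind `"background"`.
#' @param reps number of replicates to return.
#' @return list of residual `rmsd_matrix` objects.
#' @export
randomized_residuals <- function(tL, tS, reoL, reoS, background, reps = 100,
                                 seed = NULL, variant = "rate_difference",
                                 paired = TRUE) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  lapply(seq_len(reps), function(r) {
    raw <- rmsd_matrix(
      delta_profile(reoL, permute_usage(tL, rownames(reoL), paired), variant),
      delta_profile(reoS, permute_usage(tS, rownames(reoS), paired), variant))
    residual_matrix(raw, background)
  })
}

#' Structure test of the residual matrix against randomised replicates
#'
#' Tests whether the actual residual matrix carries more structure than
#' residuals from randomised usage data: for each statistic (variance and
#' mean of the matrix entries), a one-sample Z score
#' \eqn{Z = (s_{actual} - \bar{s}_{rand}) / sd(s_{rand})} is computed against
#' the replicate distribution, with a one-tailed p in the
#' actual-exceeds-randomised direction, \eqn{p = 1 - \Phi(Z)}. Because the
#' permutation distribution of a variance statistic is right-skewed, the
#' normal approximation is imperfect even under a true null; the rank-based
#' permutation probabilities are therefore reported alongside (`p_var_emp`,
#' `p_mean_emp`) and are the better-calibrated quantity.
#'
#' @param residual_actual residual `rmsd_matrix` of the observed data.
#' @param randomized_residuals list of residual matrices from randomised
#'   data (at least 2), e.g. from [randomized_residuals()].
#' @return list with `variance_actual`, `variance_rand_mean`, `z_var`,
#'   `p_var`, `mean_actual`, `mean_rand_mean`, `z_mean`, `p_mean`, `reps`.
#' @export
structure_test <- function(residual_actual, randomized_residuals) {
  if (length(randomized_residuals) < 2)
    stop("need at least 2 randomized replicates")
  vs <- vapply(randomized_residuals, function(m) stats::var(as.vector(m)),
               numeric(1))
  ms <- vapply(randomized_residuals, function(m) mean(as.vector(m)),
               numeric(1))
  if (stats::sd(vs) == 0 || stats::sd(ms) == 0)
    stop("degenerate null: randomized replicate statistics have zero sd")
  va <- stats::var(as.vector(residual_actual))
  ma <- mean(as.vector(residual_actual))
  z_var <- (va - mean(vs)) / stats::sd(vs)
  z_mean <- (ma - mean(ms)) / stats::sd(ms)
  list(variance_actual = va, variance_rand_mean = mean(vs),
       z_var = z_var, p_var = stats::pnorm(z_var, lower.tail = FALSE),
       p_var_emp = (1 + sum(vs >= va)) / (length(vs) + 1),
       mean_actual = ma, mean_rand_mean = mean(ms),
       z_mean = z_mean, p_mean = stats::pnorm(z_mean, lower.tail = FALSE),
       p_mean_emp = (1 + sum(ms >= ma)) / (length(ms) + 1),
       reps = length(randomized_residuals))
}

#' Write any RMSD-type matrix as TSV
#'
#' @param m an `rmsd_matrix` (raw, background or residual) or plain matrix.
#' @param path file path.
#' @export
write_rmsd_matrix <- function(m, path) {
  df <- data.frame(position = rownames(m), unclass(m), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  k <- attr(m, "kind")
  if (!is.null(k)) writeLines(paste0("# kind=", k), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat("RMSD matrix (", attr(x, "kind"), "): ", nrow(x), " x ", ncol(x),
      ", mean ", signif(mean(x), 4), ", variance ",
      signif(stats::var(as.vector(x)), 4), "\n", sep = "")
  invisible(x)
}
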