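#' Per-position congruence Z score
#'
#' Two-sample Z comparing the usage deltas of one amino acid at an aligned
#' pair of chronology positions:
#' \deqn{Z_c = (D_L - D_S) / \sqrt{SE_L^2 + SE_S^2}.}
#' A position is congruent when |Z_c| < 1.282 (the one-tailed 0.10 normal
#' quantile, so disagreement is not even marginally significant).
#'
#' @param dL,dS numeric: delta values at the aligned position.
#' @param seL,seS their weighted standard errors (not both zero).
#' @return the Z score.
#' @export
position_z <- function(dL, dS, seL, seS) {
  denom <- sqrt(seL^2 + seS^2)
  if (any(denom == 0 & dL != dS))
    stop("both standard errors zero with unequal deltas: infinite Z")
  z <- (dL - dS) / denom
  z[denom == 0] <- 0
  z
}

#' Weighted Z-transform (weighted Stouffer) combination
#'
#' Combines per-position Z scores into an overall congruence statistic with
#' weights given by the inverse combined error variance,
#' \eqn{w_c = 1/(SE_{L,c}^2 + SE_{S,c}^2)}:
#' \deqn{Z_w = \sum_c w_c Z_c \Big/ \sqrt{\sum_c w_c^2},}
#' with two-tailed normal probability. Under equal weights this reduces to
#' the classic Stouffer statistic \eqn{\sum Z_c / \sqrt{k}}.
#'
#' @param z vector of per-position Z scores.
#' @param w positive weights (same length).
#' @return list with `z_w` and two-tailed `p`.
#' @export
weighted_z <- function(z, w) {
  stopifnot(length(z) == length(w), length(z) >= 1)
  if (any(w <= 0)) stop("weights must be positive")
  zw <- sum(w * z) / sqrt(sum(w^2))
  list(z_w = zw, p = 2 * stats::pnorm(-abs(zw)))
}

#' Endpoint convergence score
#'
#' Measures convergence of an amino acid's usage delta toward its expected
#' value (zero) between the first and last aligned chronology positions, as
#' the change in the number of standard errors from zero:
#' \deqn{Z_V = |D_{last}|/SE_{last} - |D_{first}|/SE_{first}.}
#' The trajectory is convergent if Z_V < -1.000 and divergent if
#' Z_V > 1.000.
#'
#' @param d_first,se_first delta and SE at the first aligned position.
#' @param d_last,se_last delta and SE at the last aligned position.
#' @return the Z_V score.
#' @export
convergence_z <- function(d_first, se_first, d_last, se_last) {
  if (any(c(se_first, se_last) <= 0)) stop("standard errors must be positive")
  abs(d_last) / se_last - abs(d_first) / se_first
}

#' Congruence and convergence report across an aligned chronology pair
#'
#' For each of the 20 amino acids, computes the per-position congruence
#' scores Z_c along the alignment, the count of congruent positions
#' (|Z_c| < `z_congruent`), the weighted Z-transform combination Z_w with
#' its two-tailed p, and the endpoint convergence scores Z_V for each
#' chronology separately. Flags follow the threshold rules: `convergent`
#' when the mean of the two Z_V values is < -`z_converge`, `divergent` when
#' it is > `z_converge`, and `consistently_convergent` when at least one
#' chronology has Z_V < -`z_converge`, neither has Z_V > `z_converge`, and
#' the mean Z_V < -`z_converge`.
#'
#' @param dL,dS `delta_profile`s of the LSU and SSU chronologies.
#' @param aln a `chronology_alignment` (columns `i_L`, `i_S`).
#' @param z_congruent congruence threshold on |Z_c| (default 1.282, the
#'   one-tailed 0.10 quantile).
#' @param z_converge convergence threshold on Z_V (default 1.0).
#' @return a `congruence_report`: data frame with one row per amino acid
#'   (columns `aa`, `z_w`, `p`, `congruent`, `k`, `z_v_L`, `z_v_S`,
#'   `z_v_ave`, `convergent`, `divergent`, `consistently_convergent`) and
#'   attributes `z_v_L_ave`, `z_v_S_ave` (grand averages across amino
#'   acids), `z_c` (k x 20 matrix of per-position scores) and `alignment`.
#' @export
congruence_table <- function(dL, dS, aln, z_congruent = 1.282,
                             z_converge = 1.0) {
  iL <- aln$i_L
  iS <- aln$i_S
  if (any(iL < 1 | iL > nrow(dL$delta)) || any(iS < 1 | iS > nrow(dS$delta)))
    stop("alignment positions outside the profiles")
  k <- length(iL)
  DL <- dL$delta[iL, , drop = FALSE]; SL <- dL$se[iL, , drop = FALSE]
  DS <- dS$delta[iS, , drop = FALSE]; SS <- dS$se[iS, , drop = FALSE]
  comb_se2 <- SL^2 + SS^2
  zc <- (DL - DS) / sqrt(comb_se2)
  zc[comb_se2 == 0 & DL == DS] <- 0   # degenerate cell, trivially congruent
  w <- 1 / comb_se2
  safe_zv <- function(d1, s1, d2, s2) {
    if (s1 <= 0 || s2 <= 0) return(NA_real_)
    convergence_z(d1, s1, d2, s2)
  }
  rows <- lapply(seq_along(AMINO_ACIDS), function(a) {
    ## cells with zero combined variance carry no sampling information and
    ## are excluded from the weighted combination
    ok <- is.finite(w[, a]) & w[, a] > 0
    comb <- if (any(ok)) weighted_z(zc[ok, a], w[ok, a])
            else list(z_w = NA_real_, p = NA_real_)
    zvL <- safe_zv(DL[1, a], SL[1, a], DL[k, a], SL[k, a])
    zvS <- safe_zv(DS[1, a], SS[1, a], DS[k, a], SS[k, a])
    ave <- mean(c(zvL, zvS))
    data.frame(
      aa = AMINO_ACIDS[a], z_w = comb$z_w, p = comb$p,
      congruent = sum(abs(zc[, a]) < z_congruent), k = k,
      z_v_L = zvL, z_v_S = zvS, z_v_ave = ave,
      convergent = isTRUE(ave < -z_converge),
      divergent = isTRUE(ave > z_converge),
      consistently_convergent = isTRUE(
        (zvL < -z_converge || zvS < -z_converge) &&
        zvL <= z_converge && zvS <= z_converge && ave < -z_converge))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("congruence_report", "data.frame"),
            z_v_L_ave = mean(out$z_v_L, na.rm = TRUE),
            z_v_S_ave = mean(out$z_v_S, na.rm = TRUE),
            z_c = zc, alignment = aln)
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("Congruence/convergence report over", x$k[1], "aligned positions\n")
  df <- as.data.frame(x)
  df$p <- signif(df$p, 3)
  df$z_w <- round(df$z_w, 3)
  df$z_v_L <- round(df$z_v_L, 3)
  df$z_v_S <- round(df$z_v_S, 3)
  df$positions <- paste0(df$congruent, "/", df$k)
  print(df[, c("aa", "p", "positions", "z_v_L", "z_v_S",
               "consistently_convergent")], row.names = FALSE)
  cat(sprintf("grand averages: Z_V,L = %.3f  Z_V,S = %.3f\n",
              attr(x, "z_v_L_ave"), attr(x, "z_v_S_ave")))
  invisible(x)
}

#' Write a congruence report as TSV or JSON
#'
#' @param rep a `congruence_report`.
#' @param path destination; `.json` selects JSON (including the grand
#'   averages), otherwise a TSV mirroring the report columns is written.
#' @export
write_congruence_report <- function(rep, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(table = as.data.frame(rep),
           z_v_L_ave = attr(rep, "z_v_L_ave"),
           z_v_S_ave = attr(rep, "z_v_S_ave")),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(rep)
    df$positions <- paste0(df$congruent, "/", df$k)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
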