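#' The 20 proteinogenic amino acids (one-letter codes)
#'
#' Canonical amino-acid ordering used by every count, rate and delta matrix
#' in the package.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

aa_matrix <- function(x, proteins) {
  m <- matrix(0, length(proteins), length(AMINO_ACIDS),
              dimnames = list(protein = proteins, aa = AMINO_ACIDS))
  if (!is.null(x)) {
    x <- as.matrix(x)
    m[rownames(x), colnames(x)] <- x
  }
  m
}

#' Construct a usage table
#'
#' Per-protein amino-acid counts at universally conserved (`U`) and
#' domain-specific (`D`) positions. `U` positions are alignment sites whose
#' ancestral identity is confidently reconstructed and identical in both the
#' bacterial and the archaeal/eukaryal root; `D` positions are conserved at
#' one domain's root but not universally.
#'
#' @param U,D integer matrices (proteins x amino acids); columns are matched
#'   to [AMINO_ACIDS] by name, missing columns are zero-filled.
#' @param subunit free-text label.
#' @return a `usage_table` with fields `proteins`, `U`, `D`, `U_total`,
#'   `D_total`, `subunit`.
#' @export
usage_table <- function(U, D, subunit = "") {
  proteins <- rownames(U)
  if (is.null(proteins)) stop("U must have protein row names")
  if (!identical(rownames(D), proteins))
    stop("U and D must cover the same proteins in the same order")
  Um <- aa_matrix(U, proteins)
  Dm <- aa_matrix(D, proteins)
  if (any(Um < 0) || any(Dm < 0)) stop("counts must be nonnegative")
  structure(list(subunit = subunit, proteins = proteins, U = Um, D = Dm,
                 U_total = rowSums(Um), D_total = rowSums(Dm)),
            class = "usage_table")
}

#' @export
print.usage_table <- function(x, ...) {
  cat("Usage table", if (nzchar(x$subunit)) paste0("(", x$subunit, ")"),
      "-", length(x$proteins), "proteins\n")
  cat("  U totals:", paste(x$U_total, collapse = " "), "\n")
  cat("  D totals:", paste(x$D_total, collapse = " "), "\n")
  invisible(x)
}

#' Read / write usage tables as TSV
#'
#' One row per (protein, dataset) pair: columns `protein`, `dataset` (`U` or
#' `D`), the 20 amino-acid count columns, and `total` (recomputed and checked
#' on read).
#'
#' @param t a `usage_table`.
#' @param path file path.
#' @param subunit optional label recorded on the result.
#' @rdname usage_io
#' @export
write_usage_table <- function(t, path) {
  rows <- rbind(
    data.frame(protein = t$proteins, dataset = "U", t$U, total = t$U_total,
               check.names = FALSE),
    data.frame(protein = t$proteins, dataset = "D", t$D, total = t$D_total,
               check.names = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname usage_io
#' @export
read_usage_table <- function(path, subunit = "") {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("protein", "dataset", AMINO_ACIDS)
  if (!all(need %in% colnames(tab)))
    stop("usage table must have columns protein, dataset and the 20 amino acids")
  u <- tab[tab$dataset == "U", ]
  d <- tab[tab$dataset == "D", ]
  U <- as.matrix(u[, AMINO_ACIDS]); rownames(U) <- u$protein
  D <- as.matrix(d[, AMINO_ACIDS]); rownames(D) <- d$protein
  D <- D[rownames(U), , drop = FALSE]
  if ("total" %in% colnames(tab)) {
    if (any(rowSums(U) != u$total) || any(rowSums(D) != d$total))
      stop("stated totals disagree with the sum of counts")
  }
  usage_table(U, D, subunit = subunit)
}

#' Call conserved sites from ancestral probability profiles
#'
#' A site is called conserved when the same amino acid has reconstruction
#' probability at least `threshold` at both nodes flanking the root branch
#' (the boundary is inclusive: probabilities of exactly `threshold` count).
#'
#' @param p1,p2 numeric matrices (sites x 20 amino acids) of ancestral state
#'   probabilities at the two nodes flanking the root; rows must sum to 1.
#' @param threshold conservation probability threshold in (0, 1]; default
#'   0.90.
#' @return data frame with columns `site` and `aa` for the conserved sites.
#' @export
call_conserved <- function(p1, p2, threshold = 0.90) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  if (nrow(p1) != nrow(p2)) stop("profiles have different site counts")
  p1 <- p1[, AMINO_ACIDS, drop = FALSE]
  p2 <- p2[, AMINO_ACIDS, drop = FALSE]
  bad <- abs(rowSums(p1) - 1) > 1e-9 | abs(rowSums(p2) - 1) > 1e-9
  if (any(bad)) stop("site probability vectors must sum to 1")
  a1 <- max.col(p1, ties.method = "first")
  a2 <- max.col(p2, ties.method = "first")
  ok <- a1 == a2 &
    p1[cbind(seq_len(nrow(p1)), a1)] >= threshold &
    p2[cbind(seq_len(nrow(p2)), a2)] >= threshold
  data.frame(site = which(ok), aa = AMINO_ACIDS[a1[ok]],
             stringsAsFactors = FALSE)
}

#' Classify conserved sites as universal or domain-specific
#'
#' Sites conserved in both the bacterial and the archaeal/eukaryal root with
#' the same identity are universally conserved (`U`). Each domain's
#' remaining conserved sites form its domain-specific set; a site conserved
#' in both domains with *different* identities contributes to both domains'
#' `D` sets (it is conserved at either root but not in the common ancestor).
#'
#' @param bac,arc data frames with columns `site`, `aa` (aligned coordinate
#'   system shared between the two domains), as returned by
#'   [call_conserved()].
#' @return list with elements `U`, `D_bac`, `D_arc` (data frames `site`,
#'   `aa`) and `D` (row-bound domain-specific sites with a `domain` column).
#' @export
classify_positions <- function(bac, arc) {
  key <- function(d) paste(d$site, d$aa)
  inU <- key(bac) %in% key(arc)
  U <- bac[inU, , drop = FALSE]
  D_bac <- bac[!inU, , drop = FALSE]
  D_arc <- arc[!(key(arc) %in% key(bac)), , drop = FALSE]
  D <- rbind(
    if (nrow(D_bac)) cbind(D_bac, domain = "bacteria"),
    if (nrow(D_arc)) cbind(D_arc, domain = "archaea/eukarya"))
  if (is.null(D)) D <- data.frame(site = integer(), aa = character(),
                                  domain = character())
  rownames(U) <- rownames(D_bac) <- rownames(D_arc) <- NULL
  list(U = U, D_bac = D_bac, D_arc = D_arc, D = D)
}

#' Aggregate classified sites into a usage table
#'
#' @param classified named list, one entry per protein, each as returned by
#'   [classify_positions()].
#' @param subunit label for the resulting table.
#' @return a `usage_table`.
#' @export
tabulate_usage <- function(classified, subunit = "") {
  proteins <- names(classified)
  count_aa <- function(d) {
    v <- table(factor(d$aa, levels = AMINO_ACIDS))
    as.integer(v)
  }
  U <- t(vapply(classified, function(x) count_aa(x$U),
                integer(length(AMINO_ACIDS))))
  D <- t(vapply(classified, function(x) count_aa(x$D),
                integer(length(AMINO_ACIDS))))
  rownames(U) <- rownames(D) <- proteins
  colnames(U) <- colnames(D) <- AMINO_ACIDS
  usage_table(U, D, subunit = subunit)
}

#' Per-protein amino-acid usage rates
#'
#' Normalises the raw counts into rates: the fraction of a protein's
#' conserved positions (separately for `U` and `D`) occupied by each amino
#' acid. Each rate vector sums to one.
#'
#' @param t a `usage_table`.
#' @param proteins subset of proteins to return (default all); every
#'   returned protein must have positive `U` and `D` totals.
#' @return list with matrices `U` and `D` of rates (proteins x amino acids).
#' @export
usage_rates <- function(t, proteins = t$proteins) {
  zero <- proteins[t$U_total[proteins] == 0 | t$D_total[proteins] == 0]
  if (length(zero))
    stop("zero U or D total for protein(s): ", paste(zero, collapse = ", "))
  list(U = t$U[proteins, , drop = FALSE] / t$U_total[proteins],
       D = t$D[proteins, , drop = FALSE] / t$D_total[proteins])
}

#' Probability-weighted usage-delta profile along a chronology
#'
#' For every chronology position i and amino acid A, the weighted mean
#' difference between universal and domain-specific usage over proteins,
#' with the REO probabilities P\[j, i\] as weights:
#' \deqn{D_{iA} = \sum_j P_{ij} \, v_{jA}}
#' where, under the default `rate_difference` variant,
#' \eqn{v_{jA} = U_{jA}/U_{jT} - D_{jA}/D_{jT}} (difference in usage rates;
#' each \eqn{v_j} vector sums to zero so the profile sums to zero at every
#' position), or, under `count_quotient`, the literal count-difference
#' quotient \eqn{(U_{jA}-D_{jA})/(U_{jT}-D_{jT})}. The weighted standard
#' error combines binomial per-protein variances:
#' \deqn{SE_{iA} = \sqrt{\sum_j P_{ij}^2 \big( r^U_{jA}(1-r^U_{jA})/U_{jT} +
#'   r^D_{jA}(1-r^D_{jA})/D_{jT} \big)}.}
#'
#' @param reo a `reo_matrix` whose proteins are all present in `t` and not
#'   usage-excluded (apply [remove_excluded()] first).
#' @param t a `usage_table`.
#' @param variant `"rate_difference"` (default) or `"count_quotient"`.
#' @return a `delta_profile`: list with matrices `delta` and `se`
#'   (positions x amino acids), `variant`, and `positions`.
#' @export
delta_profile <- function(reo, t,
                          variant = c("rate_difference", "count_quotient")) {
  variant <- match.arg(variant)
  prot <- rownames(reo)
  missing <- setdiff(prot, t$proteins)
  if (length(missing))
    stop("proteins missing from the usage table: ",
         paste(missing, collapse = ", "))
  r <- usage_rates(t, prot)
  if (variant == "rate_difference") {
    v <- r$U - r$D
  } else {
    dt <- t$U_total[prot] - t$D_total[prot]
    if (any(dt == 0))
      stop("count_quotient undefined (U_total == D_total) for: ",
           paste(prot[dt == 0], collapse = ", "))
    v <- (t$U[prot, , drop = FALSE] - t$D[prot, , drop = FALSE]) / dt
  }
  varj <- r$U * (1 - r$U) / t$U_total[prot] +
    r$D * (1 - r$D) / t$D_total[prot]
  P <- t(unclass(reo))                    # positions x proteins
  delta <- P %*% v
  se <- sqrt(P^2 %*% varj)
  dimnames(delta) <- dimnames(se) <-
    list(position = seq_len(nrow(delta)), aa = AMINO_ACIDS)
  structure(list(delta = delta, se = se, variant = variant,
                 positions = seq_len(nrow(delta))),
            class = "delta_profile")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat("Usage-delta profile:", nrow(x$delta), "positions x",
      ncol(x$delta), "amino acids (variant:", x$variant, ")\n")
  invisible(x)
}

#' Write a delta profile as TSV
#'
#' Long format: position, amino acid, delta, se.
#' @param d a `delta_profile`.
#' @param path file path.
#' @export
write_delta_profile <- function(d, path) {
  long <- data.frame(
    position = rep(seq_len(nrow(x <- d$delta)), each = ncol(x)),
    aa = rep(colnames(x), nrow(x)),
    delta = as.vector(t(x)),
    se = as.vector(t(d$se)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# variant=", d$variant), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write ancestral probability profiles as TSV
#'
#' Sites in rows, the 20 amino-acid probability columns; one file per node.
#'
#' @param path file path.
#' @param p numeric matrix sites x 20.
#' @rdname profile_io
#' @export
read_ancestral_profile <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  as.matrix(tab[, AMINO_ACIDS])
}

#' @rdname profile_io
#' @export
write_ancestral_profile <- function(p, path) {
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
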