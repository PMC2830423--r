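#' Count permitted linear evolutionary orders
#'
#' A permitted linear evolutionary order (PLEO) is a total ordering of a
#' subunit's proteins in which every prerequisite binds strictly earlier than
#' its dependents, i.e. a linear extension of the binding-dependency partial
#' order. The default method counts extensions exactly by dynamic programming
#' over downward-closed subsets (O(2^n * n)); `method = "enumerate"` performs
#' an exhaustive depth-first traversal as an independent cross-check.
#'
#' Counts are exact while below 2^53 (double precision); the dynamic
#' programme is limited to `limit` proteins (memory 2^n doubles).
#'
#' @param rs an `assembly_ruleset`.
#' @param method `"dp"` (subset dynamic programming, default) or
#'   `"enumerate"` (depth-first traversal of all permitted orders).
#' @param limit maximum number of proteins accepted by the subset DP.
#' @return the number of permitted orders, as a double.
#' @examples
#' rs <- parse_ruleset(c("A:", "B: A", "C: A"))
#' count_pleos(rs)  # the fork admits A,B,C and A,C,B
#' @export
count_pleos <- function(rs, method = c("dp", "enumerate"), limit = 24L) {
  method <- match.arg(method)
  n <- length(rs$proteins)
  if (n == 0) return(1)
  if (n > limit)
    stop("rule set has ", n, " proteins, above the subset-DP limit of ", limit)
  pm <- pred_masks(rs)
  if (method == "dp") cpp_count_extensions(pm) else cpp_count_extensions_enum(pm)
}

#' Enumerate all permitted linear evolutionary orders
#'
#' Produces every linear extension of the rule set exactly once, in
#' lexicographic order of protein labels. Intended for small rule sets; the
#' count is checked against `cap` before any memory is allocated.
#'
#' @param rs an `assembly_ruleset`.
#' @param cap refuse to materialise more than this many orders.
#' @param labels return protein labels (default) instead of integer indices.
#' @return a matrix with one permitted order per row (earliest position
#'   first).
#' @export
enumerate_pleos <- function(rs, cap = 1e6, labels = TRUE) {
  n <- length(rs$proteins)
  pm <- pred_masks(rs)
  total <- cpp_count_extensions(pm)
  if (total > cap)
    stop("rule set admits ", format(total, big.mark = ","),
         " permitted orders, above the cap of ", format(cap, big.mark = ","),
         "; use sample_pleos()")
  prio <- order(rs$proteins) - 1L  # try candidates in label order
  m <- cpp_enumerate_extensions(pm, prio, total)
  if (labels) {
    out <- matrix(rs$proteins[m], nrow = nrow(m))
    colnames(out) <- paste0("pos", seq_len(n))
    out
  } else m
}

#' Sample permitted linear evolutionary orders
#'
#' Draws random permitted orders. `method = "uniform"` samples exactly
#' uniformly over all linear extensions by weighting each sequential choice
#' with the number of permitted completions (from the subset dynamic
#' programme); `method = "frontier"` picks uniformly among the currently
#' bindable proteins at each step, which is faster but non-uniform over
#' extensions and is retained for sensitivity analysis.
#'
#' @param rs an `assembly_ruleset`.
#' @param n number of orders to draw.
#' @param seed optional integer; when given, the sample is reproducible
#'   (`set.seed(seed)` is applied locally).
#' @param method `"uniform"` (default) or `"frontier"`.
#' @param labels return protein labels instead of integer indices.
#' @return matrix with one order per row.
#' @export
sample_pleos <- function(rs, n, seed = NULL,
                         method = c("uniform", "frontier"), labels = TRUE) {
  method <- match.arg(method)
  stopifnot(n >= 1)
  pm <- pred_masks(rs)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  m <- cpp_sample_extensions(pm, as.integer(n), method == "uniform")
  if (labels) {
    out <- matrix(rs$proteins[m], nrow = nrow(m))
    colnames(out) <- paste0("pos", seq_len(ncol(m)))
    out
  } else m
}

#' Ribosomal evolutionary order (REO) probability matrix
#'
#' Compiles, for every chronology position i and protein j, the probability
#' P\[j, i\] that protein j occupies position i. With `orders = NULL`
#' (default, exact mode) probabilities are computed by dynamic programming
#' without enumeration; otherwise they are frequencies over the supplied
#' orders (rows of a matrix as returned by [sample_pleos()] or
#' [enumerate_pleos()]). Rows (proteins) and columns (positions, 1-based)
#' each sum to one.
#'
#' @param rs an `assembly_ruleset`.
#' @param orders optional matrix of orders (labels or indices, one per row).
#' @param provenance optional list recorded on the result (e.g. method, n,
#'   seed); exact mode records `list(mode = "exact")`.
#' @return a `reo_matrix`: numeric matrix proteins x positions with
#'   attributes `provenance` and `orders` (the input orders, for later
#'   re-compilation by [remove_excluded()]).
#' @export
reo_matrix <- function(rs, orders = NULL, provenance = NULL) {
  n <- length(rs$proteins)
  if (is.null(orders)) {
    P <- cpp_reo_exact(pred_masks(rs), as.integer(2^n - 1))
    prov <- if (is.null(provenance)) list(mode = "exact") else provenance
  } else {
    if (is.character(orders[1])) {
      idx <- matrix(match(orders, rs$proteins), nrow = nrow(orders))
      if (anyNA(idx)) stop("orders contain proteins not in the rule set")
    } else idx <- orders
    if (ncol(idx) != n) stop("orders over inconsistent protein sets")
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      tab <- tabulate(idx[, i], nbins = n)
      P[, i] <- tab / nrow(idx)
    }
    prov <- if (is.null(provenance)) list(mode = "compiled", n = nrow(idx)) else provenance
  }
  dimnames(P) <- list(protein = rs$proteins, position = seq_len(n))
  structure(P, class = c("reo_matrix", "matrix"),
            provenance = prov, orders = orders)
}

#' Remove usage-excluded proteins from a REO matrix
#'
#' Deletes the given proteins from every underlying permitted order and lets
#' the remaining proteins close ranks, recompiling position probabilities
#' over the shortened chronology (the excluded proteins thereby receive zero
#' weight downstream). In exact mode this is done by a conditional dynamic
#' programme on the full partial order; for compiled matrices the stored
#' orders are re-tabulated.
#'
#' @param reo a `reo_matrix` built on the full protein set of `rs`.
#' @param rs the `assembly_ruleset` the matrix was built from.
#' @param drop proteins to remove; defaults to `rs$usage_excluded`.
#' @return a `reo_matrix` over the remaining proteins; returned unchanged
#'   when `drop` is empty.
#' @export
remove_excluded <- function(reo, rs, drop = rs$usage_excluded) {
  if (!length(drop)) return(reo)
  if (!setequal(rownames(reo), rs$proteins))
    stop("REO matrix was not built on the full protein set of the rule set")
  unk <- setdiff(drop, rs$proteins)
  if (length(unk)) stop("unknown protein(s): ", paste(unk, collapse = ", "))
  keep <- setdiff(rs$proteins, drop)
  orders <- attr(reo, "orders")
  prov <- attr(reo, "provenance")
  if (is.null(orders)) {
    keep_mask <- sum(2^(match(keep, rs$proteins) - 1))
    P <- cpp_reo_exact(pred_masks(rs), as.integer(keep_mask))
    dimnames(P) <- list(protein = keep, position = seq_along(keep))
    structure(P, class = c("reo_matrix", "matrix"),
              provenance = c(prov, list(excluded_removed = drop)),
              orders = NULL)
  } else {
    if (is.character(orders[1]))
      idx <- matrix(match(orders, rs$proteins), nrow = nrow(orders))
    else idx <- orders
    dropi <- match(drop, rs$proteins)
    red <- t(apply(idx, 1, function(o) o[!o %in% dropi]))
    red <- matrix(match(rs$proteins[red], keep), nrow = nrow(red))
    n <- length(keep)
    P <- matrix(0, n, n)
    for (i in seq_len(n)) P[, i] <- tabulate(red[, i], nbins = n) / nrow(red)
    dimnames(P) <- list(protein = keep, position = seq_len(n))
    structure(P, class = c("reo_matrix", "matrix"),
              provenance = c(prov, list(excluded_removed = drop)),
              orders = matrix(keep[red], nrow = nrow(red)))
  }
}

#' @export
print.reo_matrix <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("REO probability matrix:", nrow(x), "proteins x", ncol(x), "positions",
      sprintf("(%s)\n", paste(names(prov), unlist(lapply(prov, paste, collapse = ",")),
                              sep = "=", collapse = ", ")))
  print(round(unclass(x)[, seq_len(min(6, ncol(x)))], 3), ...)
  if (ncol(x) > 6) cat("...\n")
  invisible(x)
}

#' Write / read a REO matrix as TSV
#'
#' Rows are proteins, columns 1-based chronology positions; provenance is
#' stored in `#`-prefixed header lines.
#'
#' @param reo a `reo_matrix`.
#' @param path file path.
#' @rdname reo_io
#' @export
write_reo_matrix <- function(reo, path) {
  prov <- attr(reo, "provenance")
  hdr <- paste0("# ", names(prov), "=", vapply(prov, paste, "", collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("protein", colnames(reo)), collapse = "\t"), con)
  for (i in seq_len(nrow(reo)))
    writeLines(paste(c(rownames(reo)[i],
                       formatC(reo[i, ], format = "g", digits = 15)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname reo_io
#' @export
read_reo_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = body, check.names = FALSE)
  P <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(P) <- list(protein = tab[[1]], position = colnames(P))
  prov <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) prov[[kv[1]]] <- kv[2]
  }
  structure(P, class = c("reo_matrix", "matrix"), provenance = prov,
            orders = NULL)
}

#' Sampling-convergence diagnostic
#'
#' Mean absolute difference between REO matrix entries compiled from the
#' first half and the full set of sampled orders: a concrete measure of how
#' far the sampled matrix is from convergence in n.
#'
#' @param rs an `assembly_ruleset`.
#' @param orders matrix of sampled orders.
#' @return mean absolute entry difference between half- and full-sample REO
#'   matrices.
#' @export
sampling_convergence <- function(rs, orders) {
  n <- nrow(orders)
  half <- reo_matrix(rs, orders[seq_len(n %/% 2), , drop = FALSE])
  full <- reo_matrix(rs, orders)
  mean(abs(unclass(half) - unclass(full)))
}
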