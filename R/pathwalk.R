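#' Constrained monotone random walks through a residual matrix
#'
#' Each walk starts uniformly on a cell of the first row or first column
#' (the shared corner counted once), proceeds by down, right or diagonal
#' steps — with a right step forbidden immediately after a down step and a
#' down step forbidden immediately after a right step, which keeps every
#' row/column pairing in a walk exclusive — and terminates the moment it
#' occupies any cell of the last row or last column. A walk's score is the
#' mean residual value over its visited cells (lower = better alignment of
#' the two chronologies).
#'
#' @param residual an `rmsd_matrix` (kind `"residual"`) or plain numeric
#'   matrix; rows = LSU positions, columns = SSU positions.
#' @param n_walks number of walks.
#' @param seed integer seed; when `NULL` one is drawn and recorded on the
#'   result (all walks are reproducible from it).
#' @return a `walk_set`: list with `scores`, `n_walks`, `seed`, and the
#'   matrix (for deterministic replay when compiling landscapes).
#' @export
random_walks <- function(residual, n_walks, seed = NULL) {
  stopifnot(n_walks >= 1, nrow(residual) >= 1, ncol(residual) >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  scores <- cpp_walk_scores(unclass(residual), as.integer(n_walks))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(scores = scores, n_walks = as.integer(n_walks),
                 seed = as.integer(seed), matrix = unclass(residual)),
            class = "walk_set")
}

#' @export
print.walk_set <- function(x, ...) {
  cat("Walk set:", x$n_walks, "walks (seed", x$seed, "), score range [",
      signif(min(x$scores), 4), ",", signif(max(x$scores), 4), "]\n")
  invisible(x)
}

## indices (generation order) of the q-fraction best-scoring walks;
## ties broken by generation index (stable order)
select_best <- function(ws, q) {
  stopifnot(q > 0, q <= 1)
  k <- ceiling(q * ws$n_walks)
  order(ws$scores)[seq_len(k)]   # order() is stable: ties keep input order
}

#' Best-path frequency landscape
#'
#' Selects the `q`-fraction best-scoring (lowest mean residual) walks and
#' maps, for every matrix cell, the fraction of selected walks covering it:
#' the probabilistic alignment landscape of the two chronologies.
#'
#' @param walks a `walk_set` from [random_walks()].
#' @param q fraction of walks to keep (0 < q <= 1); the conventional levels
#'   are 0.05 and 0.01.
#' @return a `path_landscape`: list with `freq` (matrix of coverage
#'   fractions), `q`, `n_walks`, `seed`, `best_cells` (cells of the single
#'   best-scoring walk, ties broken by generation index) and `best_score`.
#' @export
best_paths <- function(walks, q = 0.05) {
  sel <- select_best(walks, q)
  flags <- logical(walks$n_walks)
  flags[sel] <- TRUE
  old <- globalenv()$.Random.seed
  set.seed(walks$seed)
  res <- cpp_walk_collect(walks$matrix, walks$n_walks, flags, sel[1])
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  freq <- res$freq
  dimnames(freq) <- dimnames(walks$matrix)
  structure(list(freq = freq, q = q, n_walks = walks$n_walks,
                 seed = walks$seed, best_cells = res$cells,
                 best_score = walks$scores[sel[1]]),
            class = "path_landscape")
}

#' @export
print.path_landscape <- function(x, ...) {
  cat("Path landscape: top ", 100 * x$q, "% of ", x$n_walks,
      " walks (seed ", x$seed, "), best score ", signif(x$best_score, 5),
      "\n", sep = "")
  invisible(x)
}

#' Extract a chronology alignment
#'
#' Condenses walks or a landscape into a single monotone pairwise alignment
#' of LSU and SSU chronology positions. The default `"best_walk"` mode takes
#' the cells of the single best-scoring walk verbatim; `"ridge"` mode takes,
#' for each LSU position covered by the landscape, the SSU position of
#' maximum coverage frequency, made monotone by a running maximum (a
#' heuristic summary of the landscape crest).
#'
#' Aligned positions are numbered with respect to the LSU chronology;
#' consecutive pairs sharing an LSU position are annotated as repeats
#' (label `"i(r)"` for the r-th repeat).
#'
#' @param x a `walk_set` or `path_landscape`.
#' @param mode `"best_walk"` (default) or `"ridge"` (landscapes only).
#' @return a `chronology_alignment`: data frame with columns `i_L`, `i_S`,
#'   `label`.
#' @export
extract_alignment <- function(x, mode = c("best_walk", "ridge")) {
  mode <- match.arg(mode)
  if (inherits(x, "walk_set")) x <- best_paths(x, q = min(1, 100 / x$n_walks))
  if (mode == "best_walk") {
    cells <- x$best_cells
  } else {
    covered <- which(rowSums(x$freq) > 0)
    j <- apply(x$freq[covered, , drop = FALSE], 1, which.max)
    j <- cummax(j)
    cells <- cbind(covered, j)
  }
  aln <- data.frame(i_L = cells[, 1], i_S = cells[, 2])
  rep_idx <- stats::ave(aln$i_L, aln$i_L, FUN = seq_along) - 1
  aln$label <- ifelse(rep_idx == 0, as.character(aln$i_L),
                      sprintf("%d(%d)", aln$i_L, rep_idx + 1))
  class(aln) <- c("chronology_alignment", "data.frame")
  aln
}

#' Write a chronology alignment as TSV
#'
#' @param aln a `chronology_alignment`.
#' @param path file path.
#' @export
write_alignment <- function(aln, path) {
  utils::write.table(as.data.frame(aln), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a path landscape as TSV
#'
#' @param ls a `path_landscape`.
#' @param path file path.
#' @export
write_landscape <- function(ls, path) {
  df <- data.frame(position = rownames(ls$freq), ls$freq, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# q=%g n_walks=%d seed=%d", ls$q, ls$n_walks, ls$seed),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate walk cells against the walk rules
#'
#' Checks the full set of walk invariants for a cell sequence: start in the
#' first row or column, termination on first arrival in the last row or
#' column, only the three permitted steps, the direction-change restriction,
#' and no repeated cell.
#'
#' @param cells two-column matrix of (row, column) coordinates, 1-based.
#' @param dim matrix dimensions `c(m, n)`.
#' @return `TRUE` if valid, otherwise a character description of the first
#'   violation.
#' @export
validate_walk <- function(cells, dim) {
  m <- dim[1]; n <- dim[2]
  k <- nrow(cells)
  if (cells[1, 1] != 1 && cells[1, 2] != 1)
    return("walk does not start in the first row or column")
  if (cells[k, 1] != m && cells[k, 2] != n)
    return("walk does not end in the last row or column")
  if (k > 1 && any(cells[-k, 1] == m | cells[-k, 2] == n))
    return("walk continues after reaching the last row or column")
  if (anyDuplicated(cells)) return("repeated cell")
  prev <- 0L
  for (t in seq_len(k - 1)) {
    di <- cells[t + 1, 1] - cells[t, 1]
    dj <- cells[t + 1, 2] - cells[t, 2]
    mv <- if (di == 1 && dj == 0) 1L else if (di == 0 && dj == 1) 2L
          else if (di == 1 && dj == 1) 3L else return("illegal step")
    if (prev == 1L && mv == 2L) return("right step immediately after down")
    if (prev == 2L && mv == 1L) return("down step immediately after right")
    prev <- mv
  }
  TRUE
}

#' Enumerate every legal walk of a small matrix
#'
#' Brute-force enumeration of all walks permitted by the walk rules;
#' exponential in matrix size and intended as an exact oracle for matrices
#' up to about 6 x 6.
#'
#' @param mat numeric matrix.
#' @return list with `cells` (list of two-column coordinate matrices) and
#'   `scores` (mean matrix value per walk).
#' @export
enumerate_walks <- function(mat) {
  m <- nrow(mat); n <- ncol(mat)
  walks <- list()
  recurse <- function(path, prev) {
    i <- path[nrow(path), 1]; j <- path[nrow(path), 2]
    if (i == m || j == n) {
      walks[[length(walks) + 1]] <<- path
      return()
    }
    if (prev != 2) recurse(rbind(path, c(i + 1, j)), 1)
    if (prev != 1) recurse(rbind(path, c(i, j + 1)), 2)
    recurse(rbind(path, c(i + 1, j + 1)), 3)
  }
  starts <- unique(rbind(cbind(1, seq_len(n)), cbind(seq_len(m), 1)))
  for (s in seq_len(nrow(starts)))
    recurse(matrix(starts[s, ], 1, 2), 0)
  scores <- vapply(walks, function(p) mean(mat[p]), numeric(1))
  list(cells = walks, scores = scores)
}

#' Exact minimum-score walk by dynamic programming
#'
#' Needleman-Wunsch-style exact optimum over all legal walks: for every
#' (cell, incoming direction, length) state the minimal path total is
#' propagated, and the best mean score is minimised over terminal states.
#' Serves as a deterministic cross-check of the random-walk search (the
#' landscape itself, not just the optimum, is the random walks' purpose).
#'
#' @param mat numeric matrix.
#' @return list with `score` (minimal mean residual) and `cells` (one
#'   optimal walk, as a two-column coordinate matrix).
#' @export
best_walk_exact <- function(mat) {
  m <- nrow(mat); n <- ncol(mat)
  terminal <- function(i, j) i == m || j == n
  Lmax <- m + n
  ## total[i, j, dir, len]: minimal sum over walk prefixes of `len` cells
  ## ending at non-terminal (i,j), last move dir (1 down, 2 right, 3 diag/start)
  total <- array(Inf, c(m, n, 3, Lmax))
  from <- array(NA_integer_, c(m, n, 3, Lmax, 3))
  best <- list(score = Inf, state = NULL)
  consider_terminal <- function(i, j, tot, len, prev_state) {
    sc <- (tot + mat[i, j]) / (len + 1)
    if (sc < best$score)
      best <<- list(score = sc, state = list(cell = c(i, j), prev = prev_state))
  }
  ## starts
  starts <- unique(rbind(cbind(1, seq_len(n)), cbind(seq_len(m), 1)))
  for (s in seq_len(nrow(starts))) {
    i <- starts[s, 1]; j <- starts[s, 2]
    if (terminal(i, j)) {
      if (mat[i, j] < best$score)
        best <- list(score = mat[i, j],
                     state = list(cell = c(i, j), prev = NULL))
    } else if (mat[i, j] < total[i, j, 3, 1]) {
      total[i, j, 3, 1] <- mat[i, j]   # treat start as "diag" (no restriction)
      from[i, j, 3, 1, ] <- c(0L, 0L, 0L)
    }
  }
  for (len in seq_len(Lmax - 1)) {
    for (i in seq_len(m - 1)) for (j in seq_len(n - 1)) for (d in 1:3) {
      tot <- total[i, j, d, len]
      if (!is.finite(tot)) next
      moves <- list()
      if (d != 2) moves <- c(moves, list(c(1L, 0L, 1L)))
      if (d != 1) moves <- c(moves, list(c(0L, 1L, 2L)))
      moves <- c(moves, list(c(1L, 1L, 3L)))
      for (mv in moves) {
        i2 <- i + mv[1]; j2 <- j + mv[2]
        if (terminal(i2, j2)) {
          consider_terminal(i2, j2, tot, len, c(i, j, d, len))
        } else if (tot + mat[i2, j2] < total[i2, j2, mv[3], len + 1]) {
          total[i2, j2, mv[3], len + 1] <- tot + mat[i2, j2]
          from[i2, j2, mv[3], len + 1, ] <- c(i, j, d)
        }
      }
    }
  }
  ## reconstruct: prev is a state (i, j, dir, len); from[] holds the
  ## predecessor (i, j, dir) or (0,0,0) at a walk start
  cells <- matrix(best$state$cell, 1, 2)
  prev <- best$state$prev
  while (!is.null(prev)) {
    cells <- rbind(prev[1:2], cells)
    st <- from[prev[1], prev[2], prev[3], prev[4], ]
    prev <- if (all(st == 0)) NULL else c(st, prev[4] - 1L)
  }
  dimnames(cells) <- NULL
  list(score = best$score, cells = cells)
}
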