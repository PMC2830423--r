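#' Genetic code expansion schedule
#'
#' A code schedule gives, for each amino acid, the time at which it was
#' added to the genetic code (arbitrary time units, earlier = more ancient)
#' and its baseline modern usage frequency. The default addition order
#' follows the consensus temporal order of code expansion (early: Gly, Ala,
#' Asp, Val; late: Met, Tyr, Trp), with times spread so that roughly the
#' last quarter of additions falls inside a typical recruitment window, and
#' baseline frequencies close to average modern protein composition.
#'
#' @param addition_time named numeric vector over [AMINO_ACIDS].
#' @param baseline named positive numeric vector over [AMINO_ACIDS];
#'   normalised to sum to 1.
#' @return a `code_schedule`.
#' @export
code_schedule <- function(addition_time = NULL, baseline = NULL) {
  if (is.null(addition_time)) {
    consensus <- c("G", "A", "D", "V", "S", "P", "E", "T", "L", "R",
                   "I", "Q", "N", "H", "K", "C", "F", "Y", "M", "W")
    addition_time <- stats::setNames(seq(-12, 18, length.out = 20),
                                     consensus)[AMINO_ACIDS]
  }
  if (is.null(baseline)) {
    baseline <- c(A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86,
                  G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
                  M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
                  S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92)
  }
  addition_time <- addition_time[AMINO_ACIDS]
  baseline <- baseline[AMINO_ACIDS]
  stopifnot(all(is.finite(addition_time)), all(baseline > 0))
  structure(list(addition_time = addition_time,
                 baseline = baseline / sum(baseline)),
            class = "code_schedule")
}

## imprint composition for a protein recruited at time t: amino acids not
## yet added get weight zero; added ones carry a recency penalty decaying
## with time since addition, scaled by the drift effect size. drift = 0 is
## the exact null (modern composition, no mask).
imprint_weights <- function(schedule, t, drift, tau = 5) {
  b <- schedule$baseline
  if (drift == 0) return(b)
  age <- t - schedule$addition_time
  w <- b * exp(-drift * exp(-age / tau))
  w[age < 0] <- 0
  if (all(w == 0))
    stop("no amino acid available at recruitment time ", t)
  w / sum(w)
}

#' Simulate a synthetic two-subunit world with known ground truth
#'
#' Generates a pair of subunit analogues (LSU-like and SSU-like) under a
#' known code-expansion schedule. Each subunit recruits proteins at unit
#' time steps, the LSU analogue starting `lag` steps before the SSU
#' analogue. A protein recruited at time t draws its universally conserved
#' (U) positions from a multinomial whose per-amino-acid weights mask amino
#' acids not yet added to the code and down-weight recent additions, the
#' bias decaying toward modern frequencies as the code ages (effect size
#' `drift`; `drift = 0` is the exact null in which U and D positions are
#' drawn from the same modern composition). Domain-specific (D) positions
#' are always drawn from modern frequencies. The binding-dependency DAG is
#' drawn edge-wise from earlier to later proteins with probability
#' `dep_density`, so every dependency respects recruitment order; the first
#' protein binds rRNA directly and the dependency graph is connected.
#'
#' @param n_proteins integer vector of length 2: proteins in the LSU- and
#'   SSU-analogue (default `c(15, 18)`).
#' @param lag recruitment lead of the LSU analogue, in time steps (default 3).
#' @param drift code-imprint effect size (>= 0; default 2; 0 = null world).
#' @param sites number of U and of D positions per protein (default 60
#'   each).
#' @param dep_density probability of a dependency edge from each earlier
#'   protein (default 0.20, calibrated so the median permitted-order
#'   fraction of a 15-protein subunit matches the ~1e-5 selectivity scale
#'   of the real LSU assembly map).
#' @param seed integer seed (required for reproducibility).
#' @param schedule a [code_schedule()].
#' @param tau recency-penalty decay time of the code imprint, in time steps.
#' @return a `synthetic_world`: list with elements `lsu` and `ssu` (each
#'   with `rules`, `usage`, `times`, and site-level truth `sites`) and
#'   `truth` (lag, drift, seeds, schedule).
#' @export
simulate_world <- function(n_proteins = c(15, 18), lag = 3, drift = 2,
                           sites = c(U = 60, D = 60), dep_density = 0.20,
                           seed = NULL, schedule = code_schedule(),
                           tau = 5) {
  stopifnot(all(n_proteins >= 2), drift >= 0, all(sites >= 1),
            dep_density >= 0, dep_density <= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  nU <- if (is.null(names(sites))) sites[1] else sites[["U"]]
  nD <- if (is.null(names(sites))) sites[2] else sites[["D"]]
  make_subunit <- function(n, t0, prefix) {
    times <- t0 + seq_len(n) - 1
    prots <- paste0(prefix, seq_len(n))
    ## dependency DAG respecting recruitment order
    deps <- stats::setNames(vector("list", n), prots)
    for (k in seq_len(n)) {
      if (k == 1) { deps[[k]] <- character(); next }
      sel <- stats::runif(k - 1) < dep_density
      deps[[k]] <- prots[seq_len(k - 1)][sel]
    }
    ## connectivity: link any weakly disconnected component to an
    ## earlier-recruited protein outside it (keeps edges time-respecting)
    repeat {
      rules <- ruleset(prots, deps, subunit = prefix)
      g <- ruleset_graph(rules)
      comp <- igraph::components(g, mode = "weak")$membership
      if (max(comp) == 1) break
      for (cid in setdiff(unique(comp), comp[[prots[1]]])) {
        members <- which(prots %in% names(comp)[comp == cid])
        p <- min(members)           # earliest recruit of the component
        if (p == 1) next
        donor <- sample.int(p - 1, 1)
        deps[[p]] <- c(deps[[p]], prots[donor])
      }
    }
    ## site-level truth: identities of U and D positions
    siteU <- siteD <- vector("list", n)
    U <- D <- matrix(0L, n, 20, dimnames = list(prots, AMINO_ACIDS))
    for (k in seq_len(n)) {
      wU <- imprint_weights(schedule, times[k], drift, tau)
      idsU <- sample(AMINO_ACIDS, nU, replace = TRUE, prob = wU)
      idsD <- sample(AMINO_ACIDS, nD, replace = TRUE,
                     prob = schedule$baseline)
      siteU[[k]] <- idsU
      siteD[[k]] <- idsD
      U[k, ] <- tabulate(factor(idsU, AMINO_ACIDS), 20)
      D[k, ] <- tabulate(factor(idsD, AMINO_ACIDS), 20)
    }
    list(rules = rules, usage = usage_table(U, D, subunit = prefix),
         times = stats::setNames(times, prots),
         sites = list(U = stats::setNames(siteU, prots),
                      D = stats::setNames(siteD, prots)))
  }
  lsu <- make_subunit(n_proteins[1], t0 = 0, prefix = "L")
  ssu <- make_subunit(n_proteins[2], t0 = lag, prefix = "S")
  structure(list(lsu = lsu, ssu = ssu,
                 truth = list(lag = lag, drift = drift, seed = seed,
                              dep_density = dep_density, tau = tau,
                              schedule = schedule)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world: LSU analogue", length(x$lsu$rules$proteins),
      "proteins, SSU analogue", length(x$ssu$rules$proteins),
      "proteins; lag", x$truth$lag, ", drift", x$truth$drift, "\n")
  invisible(x)
}

#' Ancestral probability profiles from a synthetic world
#'
#' Builds, for each protein, the two root-flanking-node probability profiles
#' for each domain, so the conserved-position calling stage can be exercised
#' end to end. A protein's bacterial conserved set is its U sites plus half
#' of its D sites; the archaeal/eukaryal set is the U sites plus the other
#' half (so classification recovers the world's U/D split). Each true
#' conserved site carries probability `1 - conservation_noise` on its
#' identity at both nodes (the noise spread over the remaining amino acids);
#' a fraction `decoy_frac` of additional sites gets sub-threshold
#' probabilities (0.5) and must not be called.
#'
#' @param world a `synthetic_world`.
#' @param conservation_noise in \[0, 0.5); with `1 - conservation_noise >=
#'   0.9` the true conserved sets are recovered exactly by
#'   [call_conserved()].
#' @param decoy_frac fraction of decoy sites appended (default 0.1).
#' @return nested list `[[subunit]][[protein]]` with elements `bac` and
#'   `arc`, each a list of two site x 20 probability matrices (`node1`,
#'   `node2`), plus a `sites` map of the true per-domain conserved sets.
#' @export
profiles_from_world <- function(world, conservation_noise = 0.05,
                                decoy_frac = 0.1) {
  if (conservation_noise < 0 || conservation_noise >= 0.5)
    stop("conservation_noise must be in [0, 0.5)")
  build <- function(sub) {
    out <- list()
    for (pr in sub$rules$proteins) {
      u <- sub$sites$U[[pr]]
      d <- sub$sites$D[[pr]]
      half <- seq_len(floor(length(d) / 2))
      bac_ids <- c(u, d[half])
      arc_ids <- c(u, d[-half])
      ## shared aligned coordinate system: sites 1..nU are universal, then
      ## the bacterial-specific block, then the archaeal-specific block
      nU <- length(u)
      bac_sites <- c(seq_len(nU), nU + half)
      arc_sites <- c(seq_len(nU), nU + setdiff(seq_along(d), half))
      n_total <- nU + length(d)
      n_decoy <- ceiling(decoy_frac * n_total)
      full_bac <- rep(NA_character_, n_total)
      full_bac[bac_sites] <- bac_ids
      full_arc <- rep(NA_character_, n_total)
      full_arc[arc_sites] <- arc_ids
      mk <- function(full) {
        ids <- full
        p <- matrix(1 / 20, n_total + n_decoy, 20,
                    dimnames = list(NULL, AMINO_ACIDS))
        for (s in seq_len(n_total)) {
          if (is.na(ids[s])) {
            row <- rep(0.5 / 19, 20)  # conserved in the other domain only
            row[match("A", AMINO_ACIDS)] <- 0.5
            p[s, ] <- row
          } else {
            row <- rep(conservation_noise / 19, 20)
            row[match(ids[s], AMINO_ACIDS)] <- 1 - conservation_noise
            p[s, ] <- row
          }
        }
        if (n_decoy > 0) {
          for (s in n_total + seq_len(n_decoy)) {
            row <- rep(0.5 / 19, 20)
            row[match("G", AMINO_ACIDS)] <- 0.5
            p[s, ] <- row
          }
        }
        p
      }
      out[[pr]] <- list(bac = list(node1 = mk(full_bac), node2 = mk(full_bac)),
                        arc = list(node1 = mk(full_arc), node2 = mk(full_arc)),
                        true_bac = data.frame(site = bac_sites, aa = bac_ids),
                        true_arc = data.frame(site = arc_sites, aa = arc_ids))
    }
    out
  }
  list(lsu = build(world$lsu), ssu = build(world$ssu))
}

#' Serialize a synthetic world to pipeline input files
#'
#' Writes the rule sets (text dialect), usage tables (TSV) and a truth JSON
#' into a directory, in exactly the formats the analysis pipeline reads.
#'
#' @param world a `synthetic_world`.
#' @param dir destination directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    lsu_rules = file.path(dir, "lsu_rules.txt"),
    ssu_rules = file.path(dir, "ssu_rules.txt"),
    lsu_usage = file.path(dir, "lsu_usage.tsv"),
    ssu_usage = file.path(dir, "ssu_usage.tsv"),
    truth = file.path(dir, "truth.json"))
  write_ruleset(world$lsu$rules, paths["lsu_rules"])
  write_ruleset(world$ssu$rules, paths["ssu_rules"])
  write_usage_table(world$lsu$usage, paths["lsu_usage"])
  write_usage_table(world$ssu$usage, paths["ssu_usage"])
  tr <- world$truth
  tr$schedule <- list(addition_time = as.list(tr$schedule$addition_time),
                      baseline = as.list(tr$schedule$baseline))
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
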