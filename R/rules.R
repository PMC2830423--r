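#' Construct an assembly rule set
#'
#' An assembly rule set holds the binding-dependency structure of a ribosomal
#' subunit assembly map: a set of proteins and, for each protein, the
#' prerequisite proteins that must already be bound before it can join the
#' complex. Proteins without prerequisites bind the rRNA directly. The
#' dependencies define a partial order whose linear extensions are the
#' permitted linear evolutionary orders (PLEOs).
#'
#' @param proteins character vector of unique protein identifiers, in display
#'   order. Identifiers are case-sensitive and used verbatim.
#' @param dependencies named list; `dependencies[[p]]` is the character vector
#'   of prerequisites of protein `p`. Proteins absent from the list have no
#'   prerequisites.
#' @param usage_excluded proteins carried in the ordering but given zero
#'   weight in usage averaging (e.g. proteins believed to have undergone
#'   non-orthologous displacement).
#' @param subunit free-text subunit label, e.g. `"LSU"` or `"SSU"`.
#' @return an object of class `assembly_ruleset`.
#' @seealso [parse_ruleset()], [validate_ruleset()], [count_pleos()]
#' @export
ruleset <- function(proteins, dependencies = list(), usage_excluded = character(),
                    subunit = "") {
  proteins <- as.character(proteins)
  deps <- stats::setNames(vector("list", length(proteins)), proteins)
  for (p in proteins) deps[[p]] <- character()
  for (p in names(dependencies)) {
    if (length(dependencies[[p]]))
      deps[[p]] <- as.character(dependencies[[p]])
  }
  rs <- structure(
    list(subunit = as.character(subunit)[1], proteins = proteins,
         dependencies = deps, usage_excluded = as.character(usage_excluded)),
    class = "assembly_ruleset")
  diag <- validate_ruleset(rs)
  if (length(diag)) stop("invalid rule set: ", paste(diag, collapse = "; "))
  rs
}

#' Validate an assembly rule set
#'
#' Checks the structural invariants of a rule set and returns human-readable
#' diagnostics rather than raising errors: unique protein identifiers, every
#' prerequisite declared, `usage_excluded` a subset of the proteins, and an
#' acyclic dependency graph (a cycle is reported with its member proteins).
#'
#' @param rs an `assembly_ruleset` (or a bare list with the same fields).
#' @return character vector of diagnostics; empty iff all invariants hold.
#' @export
validate_ruleset <- function(rs) {
  out <- character()
  prot <- rs$proteins
  if (anyDuplicated(prot))
    out <- c(out, paste0("duplicate protein identifier(s): ",
                         paste(unique(prot[duplicated(prot)]), collapse = ", ")))
  for (p in names(rs$dependencies)) {
    unk <- setdiff(rs$dependencies[[p]], prot)
    if (length(unk))
      out <- c(out, paste0("protein '", p, "' depends on undeclared: ",
                           paste(unk, collapse = ", ")))
    if (p %in% rs$dependencies[[p]])
      out <- c(out, paste0("cyclic dependency: ", p, " -> ", p))
  }
  unk <- setdiff(rs$usage_excluded, prot)
  if (length(unk))
    out <- c(out, paste0("usage_excluded contains unknown protein(s): ",
                         paste(unk, collapse = ", ")))
  ## cycle detection on the declared part of the graph (self-loops already
  ## reported above; igraph handles the general case)
  if (!length(out)) {
    g <- ruleset_graph(rs)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      bad <- which(comp$csize > 1)[1]
      members <- names(comp$membership)[comp$membership == bad]
      out <- c(out, paste0("cyclic dependency involving: ",
                           paste(members, collapse = ", ")))
    }
  }
  out
}

#' Dependency graph of a rule set
#'
#' @param rs an `assembly_ruleset`.
#' @return an [igraph::graph] with an edge prerequisite -> dependent.
#' @export
ruleset_graph <- function(rs) {
  edges <- character()
  for (p in names(rs$dependencies))
    for (d in rs$dependencies[[p]]) edges <- c(edges, d, p)
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(rs$proteins)
  if (length(edges)) g <- g + igraph::edges(edges)
  g
}

#' @export
print.assembly_ruleset <- function(x, ...) {
  ne <- sum(lengths(x$dependencies))
  cat("Assembly rule set", if (nzchar(x$subunit)) paste0("(", x$subunit, ")"),
      "\n  proteins:", length(x$proteins), " dependencies:", ne, "\n")
  roots <- x$proteins[lengths(x$dependencies[x$proteins]) == 0]
  cat("  direct rRNA binders:", paste(roots, collapse = ", "), "\n")
  if (length(x$usage_excluded))
    cat("  usage-excluded:", paste(x$usage_excluded, collapse = ", "), "\n")
  invisible(x)
}

## ---- text dialect ----------------------------------------------------------
## One protein per line: "NAME: dep1 dep2". An empty dependency list marks a
## direct rRNA binder. '#' starts a comment. Directive lines:
##   @subunit LABEL
##   @exclude P1 P2 ...

#' Parse a rule set from its text representation
#'
#' The dialect has one protein per line (`NAME: dep1 dep2 ...`; an empty list
#' means the protein binds rRNA directly), `#` comments, and two optional
#' directives: `@subunit LABEL` and `@exclude P1 P2 ...`.
#'
#' @param text character scalar or vector of lines.
#' @return an `assembly_ruleset`.
#' @export
parse_ruleset <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  subunit <- ""
  excluded <- character()
  proteins <- character()
  deps <- list()
  for (k in seq_along(lines)) {
    line <- sub("#.*$", "", lines[k])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, "@")) {
      tok <- strsplit(line, "[[:space:]]+")[[1]]
      if (tok[1] == "@subunit") subunit <- if (length(tok) > 1) tok[2] else ""
      else if (tok[1] == "@exclude") excluded <- c(excluded, tok[-1])
      else stop("line ", k, ": unknown directive '", tok[1], "'")
      next
    }
    if (!grepl(":", line, fixed = TRUE))
      stop("line ", k, ": expected 'NAME: dep1 dep2 ...'")
    name <- trimws(sub(":.*$", "", line))
    rest <- trimws(sub("^[^:]*:", "", line))
    if (!nzchar(name)) stop("line ", k, ": empty protein name")
    if (name %in% proteins) stop("line ", k, ": duplicate protein '", name, "'")
    proteins <- c(proteins, name)
    deps[[name]] <- if (nzchar(rest)) strsplit(rest, "[[:space:]]+")[[1]] else character()
  }
  for (p in proteins) {
    unk <- setdiff(deps[[p]], proteins)
    if (length(unk))
      stop("protein '", p, "' depends on undeclared protein(s): ",
           paste(unk, collapse = ", "))
  }
  ruleset(proteins, deps, usage_excluded = excluded, subunit = subunit)
}

#' Serialize a rule set to its text representation
#'
#' @param rs an `assembly_ruleset`.
#' @return character vector of lines; `parse_ruleset()` of the result
#'   reproduces `rs` exactly.
#' @export
format_ruleset <- function(rs) {
  out <- character()
  if (nzchar(rs$subunit)) out <- c(out, paste("@subunit", rs$subunit))
  if (length(rs$usage_excluded))
    out <- c(out, paste("@exclude", paste(rs$usage_excluded, collapse = " ")))
  for (p in rs$proteins) {
    d <- rs$dependencies[[p]]
    out <- c(out, paste0(p, ":", if (length(d)) paste0(" ", paste(d, collapse = " ")) else ""))
  }
  out
}

#' Read a rule set from a file
#'
#' Reads either the text dialect (see [parse_ruleset()]) or, for files ending
#' in `.json`, the JSON mirror with keys `subunit`, `proteins`,
#' `dependencies`, `usage_excluded`.
#'
#' @param path file path.
#' @return an `assembly_ruleset`.
#' @export
read_ruleset <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    deps <- lapply(x$dependencies, function(d) as.character(unlist(d)))
    return(ruleset(x$proteins, deps,
                   usage_excluded = as.character(unlist(x$usage_excluded)),
                   subunit = if (is.null(x$subunit)) "" else x$subunit))
  }
  parse_ruleset(readLines(path, warn = FALSE))
}

#' Write a rule set to a file
#'
#' @param rs an `assembly_ruleset`.
#' @param path destination; a `.json` suffix selects the JSON mirror,
#'   otherwise the text dialect is written.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(rs, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- list(subunit = rs$subunit, proteins = rs$proteins,
              dependencies = rs$dependencies,
              usage_excluded = rs$usage_excluded)
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(format_ruleset(rs), path)
  }
  invisible(path)
}

#' Bundled subunit rule sets
#'
#' Load the binding-dependency rule sets for the universal large (LSU) and
#' small (SSU) ribosomal subunit proteins that ship with the package (see the
#' fixture headers in `inst/extdata/` for transcription notes and the
#' validation of the LSU set against its exhaustive permitted-order count).
#'
#' @return an `assembly_ruleset`.
#' @rdname bundled_rulesets
#' @export
lsu_ruleset <- function() {
  read_ruleset(system.file("extdata", "lsu_rules.txt", package = "riboreo",
                           mustWork = TRUE))
}

#' @rdname bundled_rulesets
#' @export
ssu_ruleset <- function() {
  read_ruleset(system.file("extdata", "ssu_rules.txt", package = "riboreo",
                           mustWork = TRUE))
}

## internal: prerequisite bitmasks in protein order (bit j-1 = protein j)
pred_masks <- function(rs) {
  n <- length(rs$proteins)
  if (n > 30) stop("rule sets with more than 30 proteins are not supported")
  idx <- stats::setNames(seq_len(n), rs$proteins)
  vapply(rs$proteins, function(p) {
    d <- rs$dependencies[[p]]
    if (!length(d)) return(0L)
    as.integer(sum(bitwShiftL(1L, idx[d] - 1L)))
  }, integer(1))
}
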