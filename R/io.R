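# Plain-text I/O: the tree-sequence TSV dialect, sample sets, weights,
# phenotypes, windows and demography configs.
#
# The tree-sequence dialect is four TSV tables, either as separate texts or
# as sections of one file introduced by the marker lines "#nodes", "#edges",
# "#sites", "#mutations" (the sequence length is carried on a "#L <value>"
# line).  Headers are mandatory; other lines starting with "#" are comments;
# floats are written with full round-trip precision; a missing mutation
# parent is written as -1.

parse_tsv_text <- function(text, required, table_name, optional = character(0)) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(NULL)
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(required, hdr)
  if (length(miss) > 0)
    stopf("%s table: missing column(s) %s", table_name,
          paste(miss, collapse = ", "))
  rows <- lines[-1]
  if (length(rows) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(hdr)), hdr))
    return(out)
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != length(hdr)))
    stopf("%s table row %d: expected %d columns, found %d", table_name,
          which(nc != length(hdr))[1], length(hdr), nc[nc != length(hdr)][1])
  m <- do.call(rbind, parts)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- hdr
  out
}

num_col <- function(df, col, table_name) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  if (anyNA(x) & !anyNA(df[[col]]))
    stopf("%s table: non-numeric value in column %s", table_name, col)
  x
}

#' Load a tree sequence from table texts
#'
#' Parses the four tables from TSV texts (strings or character vectors of
#' lines) and returns a validated \code{\link{tree_sequence}}.  Empty site
#' and mutation texts yield empty tables.
#'
#' @param nodes_text TSV text with header \code{is_sample\ttime\tpopulation}
#'   (the population column may be omitted).
#' @param edges_text TSV text with header \code{left\tright\tparent\tchild}.
#' @param sites_text TSV text with header \code{position\tancestral_state},
#'   or \code{""}.
#' @param mutations_text TSV text with header
#'   \code{site\tnode\tderived_state\tparent}, or \code{""}.
#' @param L sequence length.
#' @return a \code{tree_sequence}.
#' @export
load_tree_sequence <- function(nodes_text, edges_text = "", sites_text = "",
                               mutations_text = "", L) {
  nd <- parse_tsv_text(nodes_text, c("is_sample", "time"), "nodes")
  if (is.null(nd)) stopf("nodes table is empty")
  nodes <- data.frame(is_sample = num_col(nd, "is_sample", "nodes") != 0,
                      time = num_col(nd, "time", "nodes"),
                      population = if ("population" %in% names(nd))
                        as.integer(num_col(nd, "population", "nodes")) else -1L)
  ed <- parse_tsv_text(edges_text, c("left", "right", "parent", "child"),
                       "edges")
  edges <- if (is.null(ed)) NULL else
    data.frame(left = num_col(ed, "left", "edges"),
               right = num_col(ed, "right", "edges"),
               parent = as.integer(num_col(ed, "parent", "edges")),
               child = as.integer(num_col(ed, "child", "edges")))
  st <- parse_tsv_text(sites_text, c("position", "ancestral_state"), "sites")
  sites <- if (is.null(st)) NULL else
    data.frame(position = num_col(st, "position", "sites"),
               ancestral_state = st$ancestral_state)
  mt <- parse_tsv_text(mutations_text, c("site", "node", "derived_state"),
                       "mutations")
  mutations <- if (is.null(mt)) NULL else
    data.frame(site = as.integer(num_col(mt, "site", "mutations")),
               node = as.integer(num_col(mt, "node", "mutations")),
               derived_state = mt$derived_state,
               parent = if ("parent" %in% names(mt))
                 as.integer(num_col(mt, "parent", "mutations")) else -1L)
  tree_sequence(nodes, edges, sites, mutations, L)
}

#' Read a tree sequence from a sectioned text file
#'
#' @param path file in the sectioned dialect written by
#'   \code{\link{write_tree_sequence}}.
#' @return a \code{tree_sequence}.
#' @export
read_tree_sequence <- function(path) {
  lines <- readLines(path)
  lmark <- grep("^#L\\b", lines, value = TRUE)
  if (length(lmark) != 1)
    stopf("tree sequence file must contain exactly one '#L' line")
  L <- as.numeric(strsplit(lmark, "\t", fixed = TRUE)[[1]][2])
  section <- function(name) {
    start <- which(lines == paste0("#", name))
    if (length(start) == 0) return("")
    ends <- which(grepl("^#(nodes|edges|sites|mutations)$", lines))
    stop_at <- ends[ends > start[1]]
    end <- if (length(stop_at) > 0) stop_at[1] - 1L else length(lines)
    lines[(start[1] + 1L):end]
  }
  load_tree_sequence(section("nodes"), section("edges"), section("sites"),
                     section("mutations"), L)
}

#' Write a tree sequence to a sectioned text file
#'
#' Writes the four tables with full round-trip float precision, so that
#' \code{read_tree_sequence(write_tree_sequence(ts, f))} reproduces
#' \code{ts} field for field.
#'
#' @param ts a \code{tree_sequence}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tree_sequence <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# tsdual tree sequence tables",
     paste0("#L\t", fmt_real(ts$L)))
  wl("#nodes", "is_sample\ttime\tpopulation")
  if (nrow(ts$nodes) > 0)
    wl(paste(as.integer(ts$nodes$is_sample), fmt_real(ts$nodes$time),
             ts$nodes$population, sep = "\t"))
  wl("#edges", "left\tright\tparent\tchild")
  if (nrow(ts$edges) > 0)
    wl(paste(fmt_real(ts$edges$left), fmt_real(ts$edges$right),
             ts$edges$parent, ts$edges$child, sep = "\t"))
  wl("#sites", "position\tancestral_state")
  if (nrow(ts$sites) > 0)
    wl(paste(fmt_real(ts$sites$position), ts$sites$ancestral_state,
             sep = "\t"))
  wl("#mutations", "site\tnode\tderived_state\tparent")
  if (nrow(ts$mutations) > 0)
    wl(paste(ts$mutations$site, ts$mutations$node,
             ts$mutations$derived_state, ts$mutations$parent, sep = "\t"))
  invisible(path)
}

#' Export decoded genotypes as TSV
#'
#' One row per site: the position followed by one allele column per sample.
#'
#' @param ts a \code{tree_sequence}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(ts, path) {
  g <- decode_genotypes(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("position", paste0("s", ts$samples)), collapse = "\t"),
             con)
  if (nrow(ts$sites) > 0) {
    rows <- vapply(seq_len(nrow(ts$sites)), function(j)
      paste(c(fmt_real(ts$sites$position[j]), g[j, ]), collapse = "\t"),
      character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read sample-set definitions from TSV
#'
#' Expects columns \code{set_name} and \code{sample_id}, one row per
#' membership.  Returns a named list of \code{\link{sample_set}} objects in
#' first-appearance order.
#'
#' @param path TSV file path.
#' @return named list of \code{sample_set}s.
#' @export
read_sample_sets <- function(path) {
  df <- parse_tsv_text(readLines(path), c("set_name", "sample_id"),
                       "sample sets")
  if (is.null(df)) stopf("sample-set file is empty")
  ids <- as.integer(num_col(df, "sample_id", "sample sets"))
  out <- list()
  for (nm in unique(df$set_name))
    out[[nm]] <- sample_set(nm, ids[df$set_name == nm])
  out
}

#' Read per-sample weight vectors from TSV
#'
#' Expects a \code{sample_id} column followed by one numeric column per
#' weight dimension.
#'
#' @param path TSV file path.
#' @return a \code{\link{sample_weights}} object.
#' @export
read_sample_weights <- function(path) {
  df <- parse_tsv_text(readLines(path), "sample_id", "weights")
  if (is.null(df)) stopf("weights file is empty")
  ids <- as.integer(num_col(df, "sample_id", "weights"))
  cols <- setdiff(names(df), "sample_id")
  W <- vapply(cols, function(cl) num_col(df, cl, "weights"),
              numeric(nrow(df)))
  W <- matrix(W, nrow = nrow(df), dimnames = list(NULL, cols))
  sample_weights(W, samples = ids)
}

#' Read a phenotype vector from TSV (columns sample_id, value)
#'
#' @param path TSV file path.
#' @return named numeric vector; names are sample ids.
#' @export
read_phenotype <- function(path) {
  df <- parse_tsv_text(readLines(path), c("sample_id", "value"), "phenotype")
  if (is.null(df)) stopf("phenotype file is empty")
  z <- num_col(df, "value", "phenotype")
  names(z) <- as.integer(num_col(df, "sample_id", "phenotype"))
  z
}

#' Read a demography configuration
#'
#' A small key-value text format with one directive per line:
#' \describe{
#'   \item{\code{population <id> <diploid size>}}{declare a population.}
#'   \item{\code{sample <pop id> <count>}}{samples drawn at time 0.}
#'   \item{\code{migration <from> <to> <rate>}}{initial per-lineage backward
#'     migration rate.}
#'   \item{\code{event <time> merge <from> <to>}}{at backward time, all
#'     lineages in \code{from} move to \code{to} and \code{from} closes.}
#'   \item{\code{event <time> migration_on <a> <b> <rate>} /
#'     \code{event <time> migration_off <a> <b>}}{switch symmetric migration
#'     between two populations.}
#' }
#' Lines starting with \code{#} are comments.
#'
#' @param path config file path.
#' @return a \code{\link{demography}} object.
#' @export
read_demography <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  pops <- data.frame(id = integer(0), size = numeric(0))
  samples <- integer(0)
  migration <- list()
  events <- data.frame(time = numeric(0), type = character(0),
                       a = integer(0), b = integer(0), rate = numeric(0))
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    switch(f[1],
      population = {
        pops <- rbind(pops, data.frame(id = as.integer(f[2]),
                                       size = as.numeric(f[3])))
      },
      sample = {
        samples[as.character(as.integer(f[2]))] <- as.integer(f[3])
      },
      migration = {
        migration[[length(migration) + 1]] <-
          c(as.integer(f[2]), as.integer(f[3]), as.numeric(f[4]))
      },
      event = {
        tp <- f[3]
        events <- rbind(events, data.frame(
          time = as.numeric(f[2]), type = tp,
          a = as.integer(f[4]), b = as.integer(f[5]),
          rate = if (tp == "migration_on") as.numeric(f[6]) else NA_real_))
      },
      stopf("unknown demography directive: %s", f[1]))
  }
  P <- max(pops$id)
  M <- matrix(0, P, P)
  for (m in migration) M[m[1], m[2]] <- m[3]
  sc <- integer(P)
  sc[as.integer(names(samples))] <- samples
  demography(populations = pops, sample_counts = sc, migration = M,
             events = events)
}

# Parse a windows spec: either a comma-separated breakpoint list or an
# integer count of equal windows.
parse_windows <- function(spec, num_windows, L) {
  if (!is.null(num_windows))
    return(equal_windows(L, as.integer(num_windows)))
  if (is.null(spec)) return(ts_windows(c(0, L), L))
  ts_windows(as.numeric(strsplit(spec, ",", fixed = TRUE)[[1]]), L)
}
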