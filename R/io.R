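#' Read and write networks as JSON
#'
#' The on-disk network format is a single JSON object:
#' \preformatted{
#' {"variables": [{"name": "SES", "states": ["0","1","2","3"], "level": 3},
#'                ...],
#'  "edges": [["SES", "FS"], ...],
#'  "cpts": {"FS": {"parents": ["SES"],
#'                  "table": {"0": [0.95, 0.05], "1": [0.9, 0.1], ...}}}}
#' }
#' Each table key is the comma-joined 0-based parent state indices in the
#' declared parent order (the key `"."` for parentless variables); each
#' value lists the child-state probabilities in state order. `level` is
#' optional and records the causal-ordering level when one is supplied.
#' Probabilities are written at full precision, so a save/load round trip
#' reproduces the network exactly.
#'
#' @param network a [bn].
#' @param path file path.
#' @param ordering optional [causal_ordering] stored as the variables'
#'   `level` fields.
#' @return `load_network()`: a [bn]; if the file carries levels, the
#'   reconstructed [causal_ordering] is attached as attribute `"ordering"`.
#' @export
save_network <- function(network, path, ordering = NULL) {
  str <- network$structure
  vn <- variable_names(str)
  lvl <- if (!is.null(ordering)) level_of(ordering) else NULL
  vars <- lapply(vn, function(v) {
    out <- list(name = v, states = as.list(str$vars[[v]]))
    if (!is.null(lvl) && v %in% names(lvl)) out$level <- unname(lvl[[v]])
    out
  })
  edges <- apply(str$edges, 1L, function(e) as.list(unname(e)),
                 simplify = FALSE)
  cpts <- lapply(vn, function(v) {
    cpt <- network$cpts[[v]]
    pa <- attr(cpt, "parents")
    r <- dim(cpt)[1L]
    nconf <- length(cpt) / r
    keys <- parent_config_keys(str, pa)
    tab <- lapply(seq_len(nconf), function(k)
      as.numeric(cpt[(k - 1L) * r + seq_len(r)]))
    names(tab) <- keys
    list(parents = as.list(pa), table = tab)
  })
  names(cpts) <- vn
  obj <- list(variables = vars, edges = edges, cpts = cpts)
  # I(17) significant digits: doubles survive the round trip bit-for-bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

# keys "0,0", "1,0", ... first parent fastest (column-major, matching the
# CPT array layout); "." when there are no parents (JSON objects cannot
# reliably carry an empty-string key through every serialiser)
parent_config_keys <- function(str, parents) {
  if (!length(parents)) return(".")
  card <- vapply(str$vars[parents], length, 1L)
  grid <- expand.grid(lapply(card, function(r) 0:(r - 1L)),
                      KEEP.OUT.ATTRS = FALSE)
  apply(grid, 1L, paste, collapse = ",")
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("variables", "edges", "cpts"))
    if (is.null(obj[[f]])) stop("/", f, ": missing field")
  vars <- list(); lvl <- list()
  for (i in seq_along(obj$variables)) {
    v <- obj$variables[[i]]
    if (is.null(v$name) || is.null(v$states))
      stop("/variables/", i - 1L, ": needs 'name' and 'states'")
    vars[[v$name]] <- as.character(unlist(v$states))
    if (!is.null(v$level)) lvl[[v$name]] <- as.integer(v$level)
  }
  edges <- lapply(obj$edges, function(e) {
    e <- as.character(unlist(e))
    if (length(e) != 2L) stop("/edges: each edge must be a pair")
    e
  })
  str <- bn_structure(vars, edges)
  bad <- setdiff(unique(unlist(edges)), names(vars))
  if (length(bad)) stop("/edges: unknown variable ", paste(bad, collapse = ", "))
  val <- validate_dag(str)
  if (!val$ok) stop("/edges: ", paste(val$violations, collapse = "; "))
  cpts <- list()
  for (v in names(vars)) {
    spec <- obj$cpts[[v]]
    if (is.null(spec)) stop("/cpts/", v, ": missing CPT")
    pa <- as.character(unlist(spec$parents))
    if (!identical(pa, bn_parents(str, v)))
      stop("/cpts/", v, "/parents: do not match the structure's parents")
    keys <- parent_config_keys(str, pa)
    r <- length(vars[[v]])
    vals <- numeric(r * length(keys))
    for (k in seq_along(keys)) {
      pos <- match(keys[[k]], names(spec$table))  # "" is a legal key
      row <- if (is.na(pos)) NULL else spec$table[[pos]]
      if (is.null(row)) stop("/cpts/", v, "/table/", keys[[k]], ": missing row")
      row <- as.numeric(unlist(row))
      if (length(row) != r)
        stop("/cpts/", v, "/table/", keys[[k]], ": expected ", r, " entries")
      if (abs(sum(row) - 1) > 1e-9)
        stop("/cpts/", v, "/table/", keys[[k]], ": row does not sum to 1")
      vals[(k - 1L) * r + seq_len(r)] <- row
    }
    cpts[[v]] <- vals
  }
  net <- bn(str, cpts)
  if (length(lvl) == length(vars)) {
    ranks <- sort(unique(unlist(lvl)))
    levels <- lapply(ranks, function(r) names(lvl)[unlist(lvl) == r])
    attr(net, "ordering") <- causal_ordering(levels)
  }
  net
}

#' Read a household table from CSV
#'
#' Expects a header row of variable names and 0-based integer state
#' indices. Rows containing any missing cell are dropped (complete-case
#' contract) with a message; unknown columns and out-of-range values are
#' errors naming the offending row and column.
#'
#' @param path CSV file path.
#' @param schema a named integer vector of cardinalities, a
#'   [bn_structure], or a [bn], declaring the expected columns and state
#'   ranges. If `NULL`, columns are taken as-is.
#' @return A data.frame of integer state columns.
#' @export
load_table <- function(path, schema = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  card <- schema_cardinalities(schema)
  if (!is.null(card)) {
    unknown <- setdiff(names(df), names(card))
    if (length(unknown))
      stop("unknown column: ", paste(unknown, collapse = ", "))
    miss <- setdiff(names(card), names(df))
    if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  }
  incomplete <- !stats::complete.cases(df)
  if (any(incomplete)) {
    message("dropped ", sum(incomplete), " incomplete row(s)")
    df <- df[!incomplete, , drop = FALSE]
    rownames(df) <- NULL
  }
  for (v in names(df)) {
    x <- df[[v]]
    if (!is.numeric(x) || any(x != floor(x)) || any(x < 0))
      stop("column '", v, "' must hold non-negative integer state indices")
    if (!is.null(card)) {
      bad <- which(x >= card[[v]])
      if (length(bad))
        stop("value ", x[bad[1L]], " out of range for column '", v,
             "' at row ", bad[1L])
    }
    df[[v]] <- as.integer(x)
  }
  df
}

schema_cardinalities <- function(schema) {
  if (is.null(schema)) return(NULL)
  if (inherits(schema, "bn")) schema <- schema$structure
  if (inherits(schema, "bn_structure"))
    return(vapply(schema$vars, length, 1L))
  stats::setNames(as.integer(schema), names(schema))
}

#' Read or write a causal ordering as YAML
#'
#' The file holds a single `levels` key whose value is a list of lists of
#' variable names, earliest level first.
#'
#' @param path YAML file path.
#' @param ordering a [causal_ordering].
#' @return `load_ordering()`: a [causal_ordering].
#' @export
load_ordering <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$levels)) stop("ordering file needs a 'levels' key")
  causal_ordering(lapply(obj$levels, as.character))
}

#' @rdname load_ordering
#' @export
save_ordering <- function(ordering, path) {
  yaml::write_yaml(list(levels = lapply(ordering$levels, as.list)), path)
  invisible(path)
}

#' Export a structure in Graphviz DOT format
#'
#' @param structure a [bn_structure] (or a [bn], whose structure is used).
#' @param path optional file to write.
#' @return The DOT text, invisibly when `path` is given.
#' @export
export_dot <- function(structure, path = NULL) {
  if (inherits(structure, "bn")) structure <- structure$structure
  lines <- c("digraph bbn {", "  rankdir=TB;",
             paste0("  ", variable_names(structure), ";"),
             if (nrow(structure$edges))
               paste0("  ", structure$edges[, 1L], " -> ",
                      structure$edges[, 2L], ";"),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a run manifest
#'
#' Records the command name, all parameters (including the seed) and the
#' package version so a run can be reproduced bit-for-bit.
#'
#' @param path output JSON path.
#' @param command a short command name.
#' @param params named list of parameters.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, command, params = list()) {
  obj <- list(command = command, params = params,
              version = paste0("fsbn ",
                               as.character(utils::packageVersion("fsbn"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
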