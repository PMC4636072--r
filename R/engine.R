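# Embedded relational engine backing both store backends: typed in-memory
# tables (data.table), unique and composite-unique index enforcement,
# foreign-key existence checks, and append-optimized inserts (chunk lists
# materialized lazily). Tables can be serialized to CSV to measure on-disk
# footprint.

#' Create an empty database handle
#' @return An `arm_db` environment.
#' @export
arm_db <- function() {
  db <- new.env(parent = emptyenv())
  db$tables <- new.env(parent = emptyenv())
  db$schema <- NULL
  class(db) <- "arm_db"
  db
}

empty_typed_dt <- function(colnames, rtypes) {
  cols <- stats::setNames(lapply(rtypes, function(tp) vector(tp, 0L)), colnames)
  data.table::as.data.table(cols)
}

#' Create a table in a database
#'
#' @param db Database handle.
#' @param name Table name.
#' @param columns Named character vector: column name -> storage kind
#'   (NVARCHAR/INTEGER/FLOAT).
#' @param key_col Optional key column (unique).
#' @param unique_sets List of character vectors; each is enforced unique.
#' @param notnull Character vector of NOT NULL columns.
#' @param foreign_keys List of `list(column, target_table, target_column)`.
#' @export
db_create_table <- function(db, name, columns, key_col = NULL,
                            unique_sets = list(), notnull = character(),
                            foreign_keys = list()) {
  if (!is.null(db$tables[[name]]))
    abort2("table_exists", "table already exists: %s", name)
  t <- new.env(parent = emptyenv())
  t$name <- name
  t$coltypes <- columns
  t$rtypes <- vapply(columns, storage_rtype, "")
  t$key_col <- key_col
  t$unique_sets <- unique_sets
  t$notnull <- notnull
  t$foreign_keys <- foreign_keys
  t$chunks <- list(empty_typed_dt(names(columns), t$rtypes))
  t$mat <- NULL
  t$counter <- 0L
  t$keys <- lapply(unique_sets, function(s) new.env(parent = emptyenv()))
  db$tables[[name]] <- t
  invisible(db)
}

#' Deploy a schema model into a database
#' @param db Database handle.
#' @param schema Schema model from [map_schema()].
#' @export
deploy_schema <- function(db, schema) {
  for (t in schema$tables) deploy_table(db, t)
  db$schema <- schema
  invisible(db)
}

deploy_table <- function(db, t) {
  cols <- stats::setNames(vapply(t$columns, `[[`, "", "storage_kind"),
                          vapply(t$columns, `[[`, "", "name"))
  uniq <- lapply(Filter(function(i) isTRUE(i$unique), t$indexes), `[[`, "columns")
  notnull <- vapply(Filter(function(c) !c$nullable, t$columns), `[[`, "", "name")
  db_create_table(db, t$name, cols, key_col = t$key_col,
                  unique_sets = uniq, notnull = notnull,
                  foreign_keys = t$foreign_keys)
}

table_env <- function(db, name) {
  t <- db$tables[[name]]
  if (is.null(t)) abort2("unknown_table", "no such table: %s", name)
  t
}

#' Materialized contents of a table
#' @param db Database handle.
#' @param name Table name.
#' @return A data.table (do not modify in place).
#' @export
db_table <- function(db, name) {
  t <- table_env(db, name)
  if (is.null(t$mat)) {
    t$mat <- data.table::rbindlist(t$chunks, use.names = TRUE)
    t$chunks <- list(t$mat)
  }
  t$mat
}

#' Table names present in a database
#' @param db Database handle.
#' @export
db_table_names <- function(db) ls(db$tables)

#' Next value of a table's generated-key counter
#' @param db Database handle.
#' @param name Table name.
#' @export
db_next_id <- function(db, name) {
  t <- table_env(db, name)
  t$counter <- t$counter + 1L
  t$counter
}

coerce_col <- function(x, rtype) {
  if (is.null(x)) return(vector(rtype, 0L))
  switch(rtype,
         character = as.character(x),
         integer = as.integer(x),
         double = as.numeric(x))
}

#' Insert rows into a table
#'
#' Enforces NOT NULL columns, unique (and composite-unique) indexes, and the
#' existence of foreign-key targets. Missing columns are filled with NA.
#'
#' @param db Database handle.
#' @param name Table name.
#' @param rows data.frame / named list of equal-length vectors.
#' @export
db_insert <- function(db, name, rows) {
  t <- table_env(db, name)
  rows <- as.list(rows)
  n <- max(c(0L, vapply(rows, length, 0L)))
  out <- vector("list", length(t$coltypes))
  names(out) <- names(t$coltypes)
  for (cn in names(t$coltypes)) {
    rt <- t$rtypes[[cn]]
    v <- rows[[cn]]
    out[[cn]] <- if (is.null(v)) rep(vector(rt, 1L)[NA], n) else coerce_col(v, rt)
    if (length(out[[cn]]) != n)
      abort2("ragged_insert", "column %s has %d values, expected %d",
             cn, length(out[[cn]]), n)
  }
  extra <- setdiff(names(rows), names(t$coltypes))
  if (length(extra))
    abort2("unknown_column", "unknown column(s) for %s: %s", name,
           paste(extra, collapse = ", "))
  for (cn in t$notnull) {
    if (anyNA(out[[cn]]))
      abort2("not_null", "NULL in NOT NULL column %s.%s", name, cn)
  }
  for (k in seq_along(t$unique_sets)) {
    cols <- t$unique_sets[[k]]
    key_strings <- do.call(paste, c(out[cols], sep = "\r"))
    if (anyDuplicated(key_strings))
      abort2("unique_violation", "duplicate key within insert batch on %s(%s)",
             name, paste(cols, collapse = ","))
    env <- t$keys[[k]]
    for (ks in key_strings) {
      if (!is.null(env[[ks]]))
        abort2("unique_violation", "unique index violation on %s(%s): %s",
               name, paste(cols, collapse = ","), ks)
    }
    for (ks in key_strings) env[[ks]] <- TRUE
  }
  for (fk in t$foreign_keys) {
    vals <- out[[fk$column]]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) next
    pt <- table_env(db, fk$target_table)
    pk_idx <- which(vapply(pt$unique_sets, function(s)
      identical(s, fk$target_column), TRUE))
    if (length(pk_idx)) {
      env <- pt$keys[[pk_idx[[1L]]]]
      for (v in as.character(vals))
        if (is.null(env[[v]]))
          abort2("fk_violation", "foreign key target absent: %s.%s = %s",
                 fk$target_table, fk$target_column, v)
    }
  }
  t$chunks[[length(t$chunks) + 1L]] <- data.table::as.data.table(out)
  t$mat <- NULL
  invisible(db)
}

#' Drop a table / delete all rows
#' @param db Database handle.
#' @param name Table name.
#' @export
db_drop_table <- function(db, name) {
  table_env(db, name)
  rm(list = name, envir = db$tables)
  invisible(db)
}

#' @rdname db_drop_table
#' @export
db_drop_rows <- function(db, name) {
  t <- table_env(db, name)
  t$chunks <- list(empty_typed_dt(names(t$coltypes), t$rtypes))
  t$mat <- NULL
  t$counter <- 0L
  t$keys <- lapply(t$unique_sets, function(s) new.env(parent = emptyenv()))
  invisible(db)
}

#' On-disk footprint of a database
#'
#' Serializes every table to CSV in a temporary directory and sums the file
#' sizes — an engine-neutral measure of the storage the backend needs.
#'
#' @param db Database handle.
#' @return Total bytes (numeric).
#' @export
db_size_bytes <- function(db) {
  dir <- tempfile("armdb_size_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  total <- 0
  for (name in db_table_names(db)) {
    f <- file.path(dir, paste0(name, ".csv"))
    data.table::fwrite(db_table(db, name), f)
    total <- total + file.size(f)
  }
  total
}
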