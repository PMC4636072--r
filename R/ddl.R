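# DDL rendering. Two dialects are shipped: "sqlite" (the default embedded
# target; clustered indexes are emulated by making the key column the PRIMARY
# KEY so rows order by it / by rowid, and the emulation is recorded in an SQL
# comment) and "generic-ansi" (NVARCHAR types; CLUSTERED rendered as a
# trailing comment on the index statement, since plain ANSI has no clustered
# keyword).

#' DDL dialect descriptor
#' @param name `"sqlite"` or `"generic-ansi"`.
#' @return Dialect list: `name`, `types` map, `clustered` strategy,
#'   `identifier_limit`.
#' @export
arm_dialect <- function(name = c("sqlite", "generic-ansi")) {
  name <- match.arg(name)
  switch(name,
         "sqlite" = list(
           name = "sqlite",
           types = c(NVARCHAR = "TEXT", INTEGER = "INTEGER", FLOAT = "REAL"),
           clustered = "primary_key", identifier_limit = 128L),
         "generic-ansi" = list(
           name = "generic-ansi",
           types = c(NVARCHAR = "NVARCHAR(255)", INTEGER = "INTEGER",
                     FLOAT = "FLOAT"),
           clustered = "comment", identifier_limit = 128L))
}

#' Render a relational schema to DDL text
#'
#' Emission is deterministic: identical schema and dialect yield byte-equal
#' DDL. Executing the result on an empty database reproduces the model's
#' tables, columns, indexes and foreign keys.
#'
#' @param schema Schema model.
#' @param dialect See [arm_dialect()].
#' @return A single DDL string (possibly empty for an empty schema).
#' @export
emit_ddl <- function(schema, dialect = arm_dialect("sqlite")) {
  out <- character()
  for (t in schema$tables) {
    if (nchar(t$name) > dialect$identifier_limit)
      abort2("identifier_too_long", "identifier exceeds dialect limit: %s", t$name)
    coldefs <- vapply(t$columns, function(c) {
      line <- paste0("  ", c$name, " ", dialect$types[[c$storage_kind]])
      if (!c$nullable) line <- paste0(line, " NOT NULL")
      if (identical(dialect$clustered, "primary_key") &&
          identical(c$name, t$key_col))
        line <- paste0(line, " PRIMARY KEY")
      line
    }, "")
    fkdefs <- vapply(t$foreign_keys, function(f)
      sprintf("  FOREIGN KEY (%s) REFERENCES %s(%s)",
              f$column, f$target_table, f$target_column), "")
    body <- paste(c(coldefs, fkdefs), collapse = ",\n")
    stmt <- sprintf("CREATE TABLE %s (\n%s\n);", t$name, body)
    if (identical(dialect$clustered, "primary_key"))
      stmt <- paste0("-- clustered index on ", t$key_col,
                     " emulated via PRIMARY KEY ordering\n", stmt)
    out <- c(out, stmt)
    for (i in t$indexes) {
      cols <- paste(i$columns, collapse = ", ")
      iname <- shorten_identifier(
        paste0(if (i$unique) "ux_" else "ix_", t$name, "_",
               paste(i$columns, collapse = "_")), dialect$identifier_limit)
      if (isTRUE(i$clustered)) {
        if (identical(dialect$clustered, "primary_key")) next # emulated above
        out <- c(out, sprintf("CREATE UNIQUE INDEX %s ON %s (%s); -- CLUSTERED",
                              iname, t$name, cols))
      } else {
        out <- c(out, sprintf("CREATE %sINDEX %s ON %s (%s);",
                              if (i$unique) "UNIQUE " else "", iname, t$name, cols))
      }
    }
  }
  if (!length(out)) return("")
  paste0(paste(out, collapse = "\n\n"), "\n")
}

#' Expected SQLite introspection of a schema model
#'
#' The structure [introspect_sqlite()] should report after executing
#' [emit_ddl()] output on an empty SQLite database; used as the
#' execute-and-introspect oracle.
#'
#' @param schema Schema model.
#' @return Canonical list: per table, columns (name/type/notnull/pk) and
#'   non-clustered index column sets and foreign keys.
#' @export
expected_sqlite_introspection <- function(schema) {
  d <- arm_dialect("sqlite")
  tabs <- lapply(schema$tables, function(t) list(
    name = t$name,
    columns = lapply(t$columns, function(c) list(
      name = c$name, type = unname(d$types[[c$storage_kind]]),
      notnull = !c$nullable, pk = identical(c$name, t$key_col))),
    indexes = sort(vapply(Filter(function(i) !isTRUE(i$clustered), t$indexes),
                          function(i) paste(i$columns, collapse = ","), "")),
    foreign_keys = {
      fks <- lapply(t$foreign_keys, function(f) list(
        column = f$column, target_table = f$target_table,
        target_column = f$target_column))
      fks[order(vapply(fks, `[[`, "", "column"))]
    }))
  tabs <- unname(tabs[order(names(schema$tables))])
  tabs
}

#' Execute DDL on SQLite and introspect the result
#'
#' Runs the DDL in an in-memory SQLite database through the system `python`
#' interpreter's standard-library `sqlite3` module and returns the catalog
#' (tables, columns, indexes, foreign keys) in the same canonical form as
#' [expected_sqlite_introspection()].
#'
#' @param ddl DDL text.
#' @return Canonical introspection list.
#' @export
introspect_sqlite <- function(ddl) {
  script <- system.file("tools", "sqlite_introspect.py", package = "armpersist")
  if (!nzchar(script)) abort2("missing_tool", "sqlite introspection tool not installed")
  ddl_file <- tempfile(fileext = ".sql")
  writeLines(ddl, ddl_file)
  out <- suppressWarnings(system2("python", c(script, ddl_file),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    abort2("sqlite_error", "DDL failed on sqlite: %s", paste(out, collapse = "\n"))
  res <- jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)
  lapply(res, function(t) list(
    name = t$name,
    columns = lapply(t$columns, function(c) list(
      name = c$name, type = c$type, notnull = isTRUE(c$notnull),
      pk = isTRUE(c$pk))),
    indexes = sort(unlist(t$indexes) %||% character()),
    foreign_keys = lapply(t$foreign_keys, function(f) list(
      column = f$column, target_table = f$target_table,
      target_column = f$target_column))))
}

# ---------------------------------------------------------------------------
# Migrations (NEW_VERSION, merge-and-convert)

apply_transform <- function(x, transform) {
  switch(transform,
         identity = x,
         cast_number = as.numeric(x),
         cast_text = ifelse(is.na(x), NA_character_, as.character(x)),
         abort2("unknown_transform", "unknown value transform: %s", transform))
}

column_checksum <- function(values) {
  v <- values[!is.na(values)]
  v <- sort(as.character(v), method = "radix")
  fnv1a32(paste(v, collapse = ""))
}

#' Apply a migration plan to a live database
#'
#' Copies every mapped column from the source table into the target table
#' (applying value transforms), verifies that row counts match, then drops
#' the source. A missing conversion for a not-null target column aborts
#' before any copying; a count mismatch aborts and leaves the source intact.
#'
#' @param db Database handle ([arm_db()]), already deployed with the schema
#'   holding both tables.
#' @param plan Migration plan from [merge_versions()] /
#'   [build_migration_plan()].
#' @return Report data.frame, one row per step, plus per-column checksum
#'   equality in `attr(, "checksums")`.
#' @export
apply_migration <- function(db, plan) {
  stopifnot(inherits(plan, "arm_migration_plan"))
  report <- data.frame(step = character(), ok = logical(), detail = character(),
                       stringsAsFactors = FALSE)
  note <- function(step, ok, detail = "") {
    report <<- rbind(report, data.frame(step = step, ok = ok, detail = detail,
                                        stringsAsFactors = FALSE))
  }
  src <- db_table(db, plan$source_table)
  tgt_def <- db$schema$tables[[plan$target_table]]
  if (is.null(tgt_def)) abort2("unknown_table", "target table not deployed")
  # pre-flight: every not-null target column must be covered
  covered <- vapply(plan$mapping, `[[`, "", "target")
  for (col in tgt_def$columns) {
    if (!col$nullable && !identical(col$role, "GENERATED_ID") &&
        !(col$name %in% covered))
      abort2("missing_conversion", "not-null column %s lacks a copy mapping",
             col$name)
  }
  note("create_target", TRUE, plan$target_table)
  n <- nrow(src)
  rows <- stats::setNames(vector("list", length(plan$mapping)),
                          vapply(plan$mapping, `[[`, "", "target"))
  for (m in plan$mapping)
    rows[[m$target]] <- apply_transform(src[[m$source]], m$transform)
  if (n > 0L) db_insert(db, plan$target_table, as.data.frame(rows,
                                                             stringsAsFactors = FALSE,
                                                             optional = TRUE))
  note("copy", TRUE, sprintf("%d rows", n))
  n2 <- nrow(db_table(db, plan$target_table))
  if (n2 != n) {
    db_drop_rows(db, plan$target_table)
    note("verify_counts", FALSE, sprintf("%d != %d", n2, n))
    abort2("count_mismatch", "migration row counts differ: %d vs %d", n, n2)
  }
  note("verify_counts", TRUE, as.character(n))
  sums <- vapply(plan$mapping, function(m) {
    tgt <- db_table(db, plan$target_table)[[m$target]]
    identical(column_checksum(apply_transform(src[[m$source]], m$transform)),
              column_checksum(tgt))
  }, TRUE)
  db_drop_table(db, plan$source_table)
  note("drop_source", TRUE, plan$source_table)
  attr(report, "checksums") <- stats::setNames(sums,
                                               vapply(plan$mapping, `[[`, "", "target"))
  report
}
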