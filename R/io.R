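# Columns a cell table must carry to be storable / loadable.
REQUIRED_CELL_COLS <- c("chip_id", "row", "col", "design_id", "cell_id",
                        "nuclear_area", "cell_area", "focus_score",
                        "nucleus_diameter", "touches_border", "touches_wall")

#' Screen store: the validated bundle of screen tables
#'
#' Couples the cell table, the per-unit summaries, the design (TDD) table,
#' the chip layout and an optional QC ledger with a provenance block
#' (package version, config hash, seed).  Referential integrity is
#' enforced on construction: every cell must sit on a unit present in the
#' unit table, every cell position must exist in the layout, and every
#' non-flat design referenced by the cells must have a TDD row when a
#' design table is supplied.
#'
#' @param cells cell table (see `REQUIRED_CELL_COLS` in the package source
#'   for the mandatory columns).
#' @param layout a [chip_layout()].
#' @param units optional unit table; recomputed via [aggregate_units()]
#'   when omitted.
#' @param designs optional TDD table.
#' @param ledger optional [build_ledger()] result.
#' @param config optional configuration object; hashed into provenance.
#' @param seed seed recorded in provenance.
#' @return object of class `screen_store`.
#' @export
screen_store <- function(cells, layout, units = NULL, designs = NULL,
                         ledger = NULL, config = NULL, seed = NA_integer_) {
  stopifnot(inherits(layout, "chip_layout"))
  miss <- setdiff(REQUIRED_CELL_COLS, names(cells))
  if (length(miss))
    stop("cell table missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(cells) &&
      any(cells$row < 1 | cells$row > layout$n_rows |
          cells$col < 1 | cells$col > layout$n_cols))
    stop("cells reference positions outside the layout", call. = FALSE)
  if (is.null(units)) units <- aggregate_units(cells)
  if (nrow(cells)) {
    ck <- unique(paste(cells$chip_id, cells$row, cells$col))
    uk <- paste(units$chip_id, units$row, units$col)
    orphan <- setdiff(ck, uk)
    if (length(orphan))
      stop("integrity violation: cells on units absent from the unit table: ",
           paste(utils::head(orphan, 3), collapse = "; "), call. = FALSE)
  }
  if (!is.null(designs)) {
    validate_design_table(designs)
    ref <- setdiff(unique(cells$design_id), c("FLAT", designs$design_id))
    if (length(ref))
      stop("integrity violation: designs without a TDD row: ",
           paste(utils::head(ref, 3), collapse = ", "), call. = FALSE)
  }
  structure(
    list(cells = cells, units = units, designs = designs, layout = layout,
         ledger = ledger,
         provenance = list(
           tool = "toposcreen",
           version = as.character(utils::packageVersion("toposcreen")),
           config_hash = config_hash(config),
           seed = seed,
           schema_version = "1.0")),
    class = "screen_store")
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.screen_store <- function(x, ...) {
  cat(sprintf("screen store: %d cells on %d units (%s v%s, seed %s)\n",
              nrow(x$cells), nrow(x$units), x$provenance$tool,
              x$provenance$version, format(x$provenance$seed)))
  invisible(x)
}

sorted_cells <- function(cells) {
  cells[order(cells$chip_id, cells$row, cells$col, cells$cell_id), , drop = FALSE]
}

#' Write / read a screen store
#'
#' CSV format writes a directory of plain tables (`cells.csv`,
#' `units.csv`, `designs.csv`, `layout.csv`, `ledger.csv`,
#' `provenance.json`); HDF5 format writes one `.h5` file with one group
#' per table (columnar datasets), the layout as a table group, and the
#' provenance block as a `provenance` group, with a `schema_version`
#' attribute at the root.  Row order is canonicalized (chip, row, col,
#' cell id) before writing, so identical stores serialize identically.
#'
#' @param store a [screen_store()].
#' @param path output directory (csv) or `.h5` file path (hdf5).
#' @param format `"csv"` or `"hdf5"`.
#' @return `write_features` returns (invisibly) a manifest data.frame of
#'   table row counts; `read_features` returns a `screen_store`.
#' @export
write_features <- function(store, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  stopifnot(inherits(store, "screen_store"))
  cells <- sorted_cells(store$cells)
  units <- store$units[order(store$units$chip_id, store$units$row, store$units$col), ,
                       drop = FALSE]
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(path, "cells.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(units), file.path(path, "units.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(store$designs))
      utils::write.csv(store$designs, file.path(path, "designs.csv"),
                       row.names = FALSE, quote = FALSE)
    write_layout_csv(store$layout, file.path(path, "layout.csv"))
    if (!is.null(store$ledger))
      write_ledger_csv(store$ledger, file.path(path, "ledger.csv"))
    writeLines(jsonlite::toJSON(store$provenance, auto_unbox = TRUE, pretty = TRUE,
                                na = "null"),
               file.path(path, "provenance.json"))
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    h5_write_table(cells, path, "cells")
    h5_write_table(as.data.frame(units), path, "units")
    if (!is.null(store$designs)) h5_write_table(store$designs, path, "designs")
    h5_write_table(as.data.frame(store$layout), path, "layout")
    if (!is.null(store$ledger)) h5_write_table(as.data.frame(store$ledger), path, "ledger")
    prov <- store$provenance
    prov$seed <- as.integer(prov$seed)
    rhdf5::h5createGroup(path, "provenance")
    for (nm in names(prov))
      rhdf5::h5write(if (is.na(prov[[nm]]) && is.character(prov[[nm]])) "NA" else prov[[nm]],
                     path, paste0("provenance/", nm))
    rhdf5::h5closeAll()
  }
  invisible(data.frame(
    table = c("cells", "units"),
    rows = c(nrow(cells), nrow(units)),
    config_hash = store$provenance$config_hash,
    stringsAsFactors = FALSE))
}

h5_write_table <- function(df, path, group) {
  rhdf5::h5createGroup(path, group)
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.logical(x)) x <- as.integer(x)
    if (is.factor(x)) x <- as.character(x)
    rhdf5::h5write(x, path, paste0(group, "/", nm))
  }
}

h5_read_table <- function(path, group, logical_cols = character()) {
  cols <- rhdf5::h5ls(path, recursive = TRUE)
  cols <- cols$name[cols$group == paste0("/", group)]
  out <- lapply(cols, function(nm) as.vector(rhdf5::h5read(path, paste0(group, "/", nm))))
  names(out) <- cols
  for (nm in intersect(logical_cols, cols)) out[[nm]] <- as.logical(out[[nm]])
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @rdname write_features
#' @export
read_features <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  logicals <- c("touches_border", "touches_wall")
  if (format == "csv") {
    if (!dir.exists(path)) stop("no such screen directory: ", path, call. = FALSE)
    cells <- utils::read.csv(file.path(path, "cells.csv"), stringsAsFactors = FALSE)
    layout <- read_layout_csv(file.path(path, "layout.csv"))
    designs <- if (file.exists(file.path(path, "designs.csv")))
      read_design_table(file.path(path, "designs.csv")) else NULL
    prov <- jsonlite::fromJSON(file.path(path, "provenance.json"))
  } else {
    if (!file.exists(path)) stop("no such HDF5 file: ", path, call. = FALSE)
    on.exit(rhdf5::h5closeAll())
    cells <- h5_read_table(path, "cells", logicals)
    lay_df <- h5_read_table(path, "layout")
    f <- tempfile(fileext = ".csv")
    utils::write.csv(lay_df, f, row.names = FALSE, quote = FALSE)
    layout <- read_layout_csv(f)
    unlink(f)
    groups <- unique(rhdf5::h5ls(path)$name)
    designs <- if ("designs" %in% groups) h5_read_table(path, "designs") else NULL
    prov <- as.list(h5_read_table(path, "provenance"))
  }
  for (nm in logicals)
    if (nm %in% names(cells) && !is.logical(cells[[nm]]))
      cells[[nm]] <- as.logical(cells[[nm]])
  miss <- setdiff(REQUIRED_CELL_COLS, names(cells))
  if (length(miss))
    stop("stored cell table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  scalar <- function(x, cast) if (is.null(x) || !length(x) || is.na(x)) cast(NA) else cast(x)
  store <- screen_store(cells, layout, designs = designs,
                        seed = suppressWarnings(scalar(prov$seed, as.integer)))
  store$provenance$config_hash <- scalar(prov$config_hash, as.character)
  store
}
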