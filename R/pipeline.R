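#' Pipeline configuration
#'
#' Collects every threshold and band of the QC, replicate-consistency and
#' ranking stages plus the synthesis parameters, validates their domains,
#' and rejects unknown keys.  All thresholds default to the screening
#' conventions documented on the individual stage functions.
#'
#' @param screen list of arguments for [screen_config()].
#' @param artifact_rates named rates passed to [plant_artifacts()] after
#'   generation (default: none).
#' @param diam_min,diam_max object-level nucleus diameter band, px.
#' @param tiers unit-level tier order; subset of `"iqr_count"`,
#'   `"iqr_focus"`, `"count_band"`, `"ntoc"`.  The default band-based
#'   configuration runs the count band then the NtoC percentile filter;
#'   `c("iqr_count", "iqr_focus")` is the IQR-based alternative.
#' @param count_band fixed `(lower, upper)` cells/unit band.
#' @param derive_band if `TRUE`, derive the band from CV curves
#'   ([select_count_band()]) instead of using `count_band` directly.
#' @param cv_features features for the CV curves when deriving the band.
#' @param iqr_k IQR multiplier.
#' @param ntoc_percentiles `(p_low, p_high)` percentiles.
#' @param repro_features cell features run through the replicate filter.
#' @param ad_band,snr_band acceptance bands of [dual_filter()].
#' @param n_extreme designs per class for [rank_select()].
#' @param test_fraction,val_of_test_fraction split fractions.
#' @param seed master pipeline seed.
#' @param ... rejected; catches unknown keys.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(screen = list(),
                            artifact_rates = NULL,
                            diam_min = 15, diam_max = 65,
                            tiers = c("count_band", "ntoc"),
                            count_band = c(11, 64),
                            derive_band = FALSE,
                            cv_features = c("nuclear_area", "form_factor"),
                            iqr_k = 1.5,
                            ntoc_percentiles = c(2.5, 97.5),
                            repro_features = "nuclear_area",
                            ad_band = c(0.05, 1),
                            snr_band = c(2, 20),
                            n_extreme = 90,
                            test_fraction = 0.20,
                            val_of_test_fraction = 0.20,
                            seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  if (diam_min >= diam_max) stop("diam_min must be below diam_max", call. = FALSE)
  bad_tier <- setdiff(tiers, c("iqr_count", "iqr_focus", "count_band", "ntoc"))
  if (length(bad_tier)) stop("unknown tier(s): ", paste(bad_tier, collapse = ", "), call. = FALSE)
  if (count_band[1] > count_band[2] || count_band[1] < 1)
    stop(sprintf("invalid count band (%g, %g)", count_band[1], count_band[2]), call. = FALSE)
  if (!(ntoc_percentiles[1] >= 0 && ntoc_percentiles[1] < ntoc_percentiles[2] &&
        ntoc_percentiles[2] <= 100))
    stop("invalid NtoC percentiles", call. = FALSE)
  if (ad_band[1] < 0 || ad_band[2] > 1 || ad_band[1] >= ad_band[2])
    stop("invalid AD p-value band", call. = FALSE)
  if (snr_band[1] >= snr_band[2]) stop("invalid SNR band", call. = FALSE)
  structure(
    list(screen = screen, artifact_rates = artifact_rates,
         diam_min = diam_min, diam_max = diam_max,
         tiers = tiers, count_band = count_band, derive_band = derive_band,
         cv_features = cv_features, iqr_k = iqr_k,
         ntoc_percentiles = ntoc_percentiles,
         repro_features = repro_features, ad_band = ad_band,
         snr_band = snr_band, n_extreme = n_extreme,
         test_fraction = test_fraction,
         val_of_test_fraction = val_of_test_fraction,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Run the full screen pipeline
#'
#' Orchestrates the stages end to end: synthesize (or load) the screen,
#' apply the object-level filters, aggregate to units, run the configured
#' unit-level QC tiers with ledger accounting, run the replicate-
#' consistency filter, rank and label the surviving designs and produce
#' the nested stratified split plus standardized model matrix.  All
#' tables, the ledger, the removal report and a structured log are written
#' into `out_dir`; every stage failure aborts with the stage name, leaving
#' a `FAILED` marker next to any partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @param store optional pre-loaded [screen_store()]; when supplied the
#'   synthesis stage is skipped.
#' @return (invisibly) a list with `store`, `ledger`, `reports`,
#'   `selection`, `split`, `model`, `paths`.
#' @export
run_pipeline <- function(config, out_dir, store = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  log_event <- function(stage, event, ...) {
    kv <- c(...)
    line <- paste0("stage=", stage, " event=", event,
                   if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=", collapse = " ")) else "")
    log_lines <<- c(log_lines, line)
  }
  stage <- "init"
  on_fail <- function(e) {
    writeLines(c(log_lines, paste0("stage=", stage, " event=FAILED msg=", conditionMessage(e))),
               log_path)
    file.create(file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  res <- tryCatch({
    stage <- "synthesize"
    if (is.null(store)) {
      cfg <- do.call(screen_config, c(config$screen, list(seed = config$seed)))
      scr <- generate_screen(cfg)
      if (!is.null(config$artifact_rates))
        scr <- plant_artifacts(scr, config$artifact_rates, seed = config$seed + 2L)
      cells <- scr$cells; layout <- scr$layout
    } else {
      scr <- NULL
      cells <- store$cells; layout <- store$layout
    }
    log_event(stage, "done", c(cells = nrow(cells)))

    stage <- "object_qc"
    images_in <- nrow(unique(cells[c("chip_id", "row", "col")]))
    objects_in <- nrow(cells)
    obj <- filter_objects(cells, config$diam_min, config$diam_max)
    cells <- obj$retained
    tiers <- list(obj$tier)
    log_event(stage, "removed", c(objects = nrow(obj$removed)))

    stage <- "unit_qc"
    units <- aggregate_units(cells)
    removal_logs <- list()
    thresholds <- list()
    for (tier_name in config$tiers) {
      r <- switch(tier_name,
        iqr_count = iqr_unit_filter(units, "cell_count", k = config$iqr_k),
        iqr_focus = iqr_unit_filter(units, "focus_score", k = config$iqr_k),
        count_band = {
          band <- if (config$derive_band) {
            curves <- lapply(config$cv_features, function(f) cv_by_count(units, f))
            select_count_band(curves, fallback = config$count_band)
          } else count_band(config$count_band[1], config$count_band[2], "fixed")
          count_band_filter(units, band)
        },
        ntoc = ntoc_percentile_filter(units, config$ntoc_percentiles[1],
                                      config$ntoc_percentiles[2])
      )
      thresholds[[tier_name]] <- r[setdiff(names(r), c("retained", "removed", "tier"))]
      if (nrow(r$removed))
        removal_logs[[tier_name]] <- data.frame(
          chip_id = r$removed$chip_id, row = r$removed$row, col = r$removed$col,
          tier = r$tier$name, stringsAsFactors = FALSE)
      units <- r$retained
      tiers <- c(tiers, list(r$tier))
      log_event(stage, r$tier$name,
                c(images = r$tier$images_removed, objects = r$tier$objects_removed))
    }
    keep <- paste(cells$chip_id, cells$row, cells$col) %in%
      paste(units$chip_id, units$row, units$col)
    cells <- cells[keep, , drop = FALSE]
    ledger <- build_ledger(tiers, images_in, objects_in)

    stage <- "replicate_qc"
    reports <- list()
    retained_designs <- setdiff(unique(cells$design_id), "FLAT")
    for (f in config$repro_features) {
      groups <- replicate_groups(cells, layout, feature = f, mode = "cell")
      groups <- groups[names(groups) %in% retained_designs]
      testable <- vapply(groups, function(g)
        sum(vapply(g, length, integer(1)) >= 2) >= 2, logical(1))
      flt <- dual_filter(groups[testable], feature = f,
                         ad_band = config$ad_band, snr_band = config$snr_band)
      reports[[f]] <- flt$report
      retained_designs <- intersect(retained_designs,
                                    c(flt$retained, names(groups)[!testable]))
      log_event(stage, f, c(removed = length(flt$removed)))
    }
    cells <- cells[cells$design_id %in% c(retained_designs, "FLAT"), , drop = FALSE]
    units <- units[units$design_id %in% c(retained_designs, "FLAT"), , drop = FALSE]

    stage <- "rank_split"
    readout <- tapply(units$cell_count, units$design_id, mean)
    readout <- readout[names(readout) != "FLAT"]
    n_extreme <- min(config$n_extreme, floor(length(readout) / 2))
    selection <- rank_select(stats::setNames(as.numeric(readout), names(readout)),
                             n_extreme = n_extreme)
    split <- nested_split(selection, config$test_fraction,
                          config$val_of_test_fraction, seed = config$seed)
    tdds <- synthetic_design_table(sort(names(readout)), seed = config$seed + 3L)
    model <- export_model_matrix(split, tdds)
    log_event(stage, "selected", c(designs = nrow(selection)))

    stage <- "write"
    out_store <- screen_store(cells, layout, designs = tdds, ledger = ledger,
                              config = config, seed = config$seed)
    write_features(out_store, file.path(out_dir, "screen"), format = "csv")
    write_ledger_csv(ledger, file.path(out_dir, "ledger.csv"))
    utils::write.csv(removal_report(reports), file.path(out_dir, "removal_report.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(split), file.path(out_dir, "split.csv"),
                     row.names = FALSE, quote = FALSE)
    if (length(removal_logs))
      utils::write.csv(do.call(rbind, removal_logs), file.path(out_dir, "unit_removals.csv"),
                       row.names = FALSE, quote = FALSE)
    log_event(stage, "done",
              c(images_retained = ledger_totals(ledger)$images_retained,
                objects_retained = ledger_totals(ledger)$objects_retained))
    writeLines(log_lines, log_path)

    list(store = out_store, ledger = ledger, reports = reports,
         selection = selection, split = split, model = model,
         thresholds = thresholds,
         paths = list(dir = out_dir, log = log_path))
  }, error = on_fail)
  invisible(res)
}
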