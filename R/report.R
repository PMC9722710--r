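#' Run the full base-case analysis
#'
#' Evaluates every strategy at every available rate variant (seven columns in
#' the shipped base case: OC alone at its point estimate; the enzyme-inducer
#' and enzyme-neutral strategies at point, lower-CI and upper-CI rates) and
#' the two incremental comparisons (strategy 2 vs strategy 1 and strategy 2
#' vs strategy 3, when present). Deterministic given the configuration.
#'
#' @param cfg A [model_config()].
#' @return A `report_bundle`: list with `results` (named list of
#'   `strategy_bundle`s), `incrementals` (named list of
#'   `incremental_result`s), and `meta` (config hash, seed, package
#'   version, timestamp).
#' @examples
#' bundle <- run_base_case(load_config(ddi_example_config()))
#' bundle$incrementals[[1]]$delta_up  # 20
#' @export
run_base_case <- function(cfg) {
  stop_on_violations(validate_config(cfg))
  results <- lapply(cfg$strategies, evaluate_strategy_bundle, cfg = cfg)
  names(results) <- vapply(cfg$strategies, `[[`, character(1), "name")

  incrementals <- list()
  if (length(results) >= 2L) {
    inc <- compare_strategies(results[[2]], results[[1]])
    incrementals[[paste0(inc$comparator, " vs ", inc$reference)]] <- inc
  }
  if (length(results) >= 3L) {
    inc <- compare_strategies(results[[2]], results[[3]])
    incrementals[[paste0(inc$comparator, " vs ", inc$reference)]] <- inc
  }

  structure(
    list(results = results, incrementals = incrementals,
         meta = list(config_hash = config_hash(cfg),
                     seed = cfg$settings$seed,
                     package_version =
                       as.character(utils::packageVersion("ddiburden")),
                     timestamp = format(Sys.time(), tz = "UTC"))),
    class = "report_bundle")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# column order: strategies in config order, variants point/low/high
bundle_columns <- function(bundle) {
  cols <- list()
  for (sname in names(bundle$results))
    for (variant in c("point", "low", "high"))
      if (!is.null(bundle$results[[sname]][[variant]]))
        cols[[paste0(sname, " [", variant, "]")]] <-
          bundle$results[[sname]][[variant]]
  cols
}

fmt_range <- function(totals, row) {
  sprintf("%s (%s-%s)", format_dollar(totals[row, "median"]),
          format_dollar(totals[row, "min"]), format_dollar(totals[row, "max"]))
}

# long-form numeric table underlying both render formats
bundle_cells <- function(bundle) {
  cols <- bundle_columns(bundle)
  rows <- list()
  row_label <- c(
    birth = "births", induced_abortion = "induced abortions",
    spontaneous_abortion = "spontaneous abortions",
    ectopic = "ectopic pregnancies")
  add <- function(label, values) rows[[length(rows) + 1L]] <<-
    c(list(row = label), values)

  add("Failure rate per 100 woman-years",
      lapply(cols, function(r) r$rate))
  for (nm in OUTCOME_STATES) {
    add(sprintf("Number of %s (n)", row_label[[nm]]),
        lapply(cols, function(r) r$events$display$outcomes[[nm]]))
    add(sprintf("Total cost of %s (USD), median (range)", row_label[[nm]]),
        lapply(cols, function(r) fmt_range(r$costs_unadjusted, nm)))
  }
  add("Total number of unintended pregnancies (n)",
      lapply(cols, function(r) r$events$display$total_up))
  add("Total cost of unintended pregnancies (unadjusted) (USD), median (range)",
      lapply(cols, function(r) fmt_range(r$costs_unadjusted, "total")))
  add("Total cost of unintended pregnancies (adjusted) (USD), median (range)",
      lapply(cols, function(r) fmt_range(r$costs_adjusted, "total")))
  list(header = c("", names(cols)), rows = rows)
}

#' Render base-case results as a table
#'
#' Emits the seven-column results layout: one count row and one
#' "median (min-max)" cost row per outcome, then the totals. Counts are
#' integers (rounded half away from zero); dollar cells are rounded to the
#' nearest dollar for display only, with ranges joined by a plain hyphen.
#' CSV and markdown renderings carry identical numeric values.
#'
#' @param bundle A `report_bundle` from [run_base_case()].
#' @param format `"markdown"` or `"csv"`.
#' @return The rendered document as a single character string.
#' @export
render_table <- function(bundle, format = c("markdown", "csv")) {
  format <- match.arg(format)
  cells <- bundle_cells(bundle)
  footnote <- paste("Counts are expected events rounded half away from zero;",
                    "cost cells use unrounded expected counts and are",
                    "rounded to the nearest dollar for display.")
  if (format == "csv") {
    tc <- textConnection("csv_out", "w", local = TRUE)
    utils::write.table(
      do.call(rbind, c(list(cells$header),
                       lapply(cells$rows, function(r)
                         vapply(r, function(x) as.character(x), character(1))))),
      tc, sep = ",", row.names = FALSE, col.names = FALSE, qmethod = "double")
    close(tc)
    return(paste0(paste(csv_out, collapse = "\n"), "\n# ", footnote, "\n"))
  }
  widths <- pmax(nchar(cells$header),
                 apply(vapply(cells$rows, function(r)
                   vapply(r, function(x) nchar(as.character(x)), numeric(1)),
                   numeric(length(cells$header))), 1, max))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  line <- function(vals) paste0(
    "| ", paste(mapply(pad, vals, widths), collapse = " | "), " |")
  paste0(paste(c(line(cells$header),
                 line(vapply(widths, function(w)
                   paste(rep("-", w), collapse = ""), character(1))),
                 vapply(cells$rows, line, character(1))),
               collapse = "\n"),
         "\n\n", footnote, "\n")
}

#' Write rendered reports and metadata to a directory
#'
#' Writes `results.csv` and `results.md` (byte-identical across repeated
#' calls on the same configuration), an `incrementals.csv` with the
#' between-strategy differences, and a `meta.json` sidecar carrying the
#' config hash, seed, package version and timestamp (the only place a
#' timestamp appears).
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "markdown")`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir, formats = c("csv", "markdown")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if ("csv" %in% formats)
    writeLines(render_table(bundle, "csv"), file.path(dir, "results.csv"))
  if ("markdown" %in% formats)
    writeLines(render_table(bundle, "markdown"), file.path(dir, "results.md"))
  if (length(bundle$incrementals)) {
    inc <- do.call(rbind, lapply(bundle$incrementals, function(x)
      data.frame(comparison = paste(x$comparator, "vs", x$reference),
                 delta_up = x$delta_up,
                 unadj_median = x$unadjusted["median"],
                 unadj_min = x$unadjusted["min"],
                 unadj_max = x$unadjusted["max"],
                 adj_median = x$adjusted["median"],
                 adj_min = x$adjusted["min"],
                 adj_max = x$adjusted["max"],
                 row.names = NULL)))
    utils::write.csv(inc, file.path(dir, "incrementals.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(render_table(x, "markdown"))
  for (inc in x$incrementals) print(inc)
  invisible(x)
}
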