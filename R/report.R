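# Result serialization mirroring the published table layouts, plus a run
# manifest with a reorder-stable configuration hash.

fmt_gbp <- function(x) as.character(round(x))
fmt_qaly <- function(x) sprintf("%.2f", x)

base_case_table <- function(det, config) {
  ref <- det$arm_results[[det$reference]]
  header_row <- data.frame(
    comparator = config$arms[[det$reference]]$name,
    cost_per_patient = fmt_gbp(ref$discounted_cost),
    qalys_per_patient = fmt_qaly(ref$discounted_qalys),
    icer = "",
    nmb = "",
    stringsAsFactors = FALSE
  )
  cmp <- det$comparisons
  icer_str <- ifelse(cmp$icer_class == "dominant", "Dominant",
                     ifelse(cmp$icer_class == "dominated", "Dominated",
                            fmt_gbp(cmp$icer_value)))
  rows <- data.frame(
    comparator = cmp$comparator,
    cost_per_patient = fmt_gbp(cmp$cost_per_patient),
    qalys_per_patient = fmt_qaly(cmp$qalys_per_patient),
    icer = icer_str,
    nmb = fmt_gbp(cmp$nmb),
    stringsAsFactors = FALSE
  )
  rbind(header_row, rows)
}

#' Write a results table as delimited text
#'
#' Serializes results in the published column layouts: the base case as
#' `comparator, cost_per_patient, qalys_per_patient, icer, nmb` (costs to
#' the nearest pound, QALYs to 2 decimal places, `"Dominant"` where the
#' reference dominates), the PSA as
#' `comparator, average_nmb, prob_cost_effective_pct` (probability to one
#' decimal place), and scenarios as the base-case layout with a leading
#' `scenario` column. Rounding happens only at serialization; internal
#' arithmetic is full precision.
#'
#' @param results Output of [run_deterministic_case()], [run_psa()], or
#'   [run_scenarios()], matching `layout`.
#' @param layout `"base_case"`, `"psa"`, or `"scenario"`.
#' @param path Output file (CSV, UTF-8, header row).
#' @param config Configuration used (needed for the base-case reference
#'   row).
#' @return The formatted data.frame, invisibly.
#' @export
write_results_table <- function(results, layout = c("base_case", "psa", "scenario"),
                                path, config = default_config()) {
  layout <- match.arg(layout)
  if (is.null(results) || length(results) == 0) {
    stop("results are empty; no table written")
  }
  tab <- switch(layout,
    base_case = {
      if (is.null(results$comparisons) || nrow(results$comparisons) == 0) {
        stop("results are empty; no table written")
      }
      base_case_table(results, config)
    },
    psa = {
      s <- results$summary
      if (is.null(s) || nrow(s) == 0) stop("results are empty; no table written")
      data.frame(
        comparator = s$comparator,
        average_nmb = fmt_gbp(s$average_nmb),
        prob_cost_effective_pct = sprintf("%.1f", 100 * s$prob_cost_effective),
        stringsAsFactors = FALSE
      )
    },
    scenario = {
      if (is.null(results$results) || length(results$results) == 0) {
        stop("results are empty; no table written")
      }
      tabs <- lapply(names(results$results), function(nm) {
        cbind(scenario = nm, base_case_table(results$results[[nm]], config),
              row.names = NULL)
      })
      do.call(rbind, tabs)
    }
  )
  write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(tab)
}

sort_fields <- function(x) {
  if (is.data.frame(x)) {
    return(lapply(x[order(names(x))], identity))
  }
  if (is.list(x)) {
    nms <- names(x)
    if (!is.null(nms) && all(nzchar(nms))) {
      x <- x[order(nms)]
    }
    return(lapply(x, sort_fields))
  }
  x
}

#' Hash a configuration
#'
#' MD5 of the canonical (recursively name-sorted) JSON serialization, so
#' the hash is stable under field reordering and changes iff any field
#' value changes.
#'
#' @param config Model configuration.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  canon <- jsonlite::toJSON(sort_fields(unclass(config)), auto_unbox = TRUE,
                            digits = 15)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records the configuration hash, package version, seeds, timestamp, and
#' the files a run emitted, as JSON alongside the outputs.
#'
#' @param config Configuration of the run.
#' @param files Character vector of emitted files.
#' @param seed Seed(s) used, if any.
#' @param path Optional JSON file to write.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(config, files, seed = NULL, path = NULL) {
  manifest <- list(
    config_hash = config_hash(config),
    package_version = as.character(packageVersion("parkcem")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.character(files)
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
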