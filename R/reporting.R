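pipeline_default_settings <- function() {
  list(band_maturity = 1.0, band_hit = 0.5)
}

#' Load a study configuration file
#'
#' Reads a YAML (or empty) configuration and merges it over the defaults,
#' which reproduce the reference study scale: 193 boys measured annually at
#' 8-18 years and 199 girls at 8-16 years. Unknown keys are rejected by
#' name; partial nested overrides (e.g. only `aphv_boys: {mean: 14.2}`) are
#' merged into the default vectors.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list with `cohort` (a [cohort_config()]) and `pipeline`
#'   (band widths).
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path),
            class = "phvalid_config_error")
    }
    user <- yaml::read_yaml(path) %||% list()
  }
  cohort_defaults <- formals(cohort_config)
  cohort_keys <- names(cohort_defaults)
  pipe_keys <- names(pipeline_default_settings())
  unknown <- setdiff(names(user), c(cohort_keys, pipe_keys))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "phvalid_config_error")
  }
  cohort_args <- user[intersect(names(user), cohort_keys)]
  # vector-valued keys (aphv_boys etc.) may arrive as named lists from
  # YAML; merge element-wise over the defaults
  for (k in names(cohort_args)) {
    def <- eval(cohort_defaults[[k]])
    v <- cohort_args[[k]]
    if (is.list(v) || (!is.null(names(v)) && length(def) > 1)) {
      merged <- def
      bad <- setdiff(names(v), names(def))
      if (length(bad) > 0) {
        abort(paste0("unknown config key(s): ", k, ".",
                     paste(bad, collapse = paste0(", ", k, "."))),
              class = "phvalid_config_error")
      }
      merged[names(v)] <- unlist(v)
      cohort_args[[k]] <- merged
    }
  }
  pipeline <- utils::modifyList(pipeline_default_settings(),
                                user[intersect(names(user), pipe_keys)])
  list(cohort = do.call(cohort_config, cohort_args), pipeline = pipeline)
}

round_df <- function(d, digits = 2) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) round(x, digits))
  d
}

#' Write a validation report bundle to disk
#'
#' Writes the descriptive tables (table1-table6 analogues), Bland-Altman
#' tables, spread statistics and a run manifest as CSV/JSON under `outdir`.
#' Ages, offsets and APHV are reported to 2 decimals; internal computation
#' stays full precision. The file set is deterministic: identical bundle
#' and seed give identical bytes (wall-clock time goes to a separate
#' `run_log.txt`, which is outside the determinism contract).
#'
#' @param bundle A `"phv_validation"` object from [run_validation()].
#' @param outdir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @param config_hash Optional config digest recorded in the manifest.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(bundle, outdir, seed = NA_integer_,
                         config_hash = "") {
  stopifnot(inherits(bundle, "phv_validation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(
    table1.csv = bundle$by_ca |> filter(.data$sex == "M"),
    table2.csv = bundle$by_ca |> filter(.data$sex == "F"),
    table3.csv = bundle$by_phv |> filter(.data$sex == "M"),
    table4.csv = bundle$by_phv |> filter(.data$sex == "F"),
    table5.csv = bundle$hits_ca,
    table6.csv = bundle$hits_phv,
    ba_ca.csv = bundle$ba_ca,
    ba_phv.csv = bundle$ba_phv,
    spread.csv = bundle$spread,
    subjects.csv = bundle$subjects)
  files <- character(0)
  for (nm in names(tabs)) {
    f <- file.path(outdir, nm)
    write.csv(round_df(as.data.frame(tabs[[nm]])), f, row.names = FALSE)
    files <- c(files, f)
  }
  counts <- bundle$subjects |>
    count(.data$sex, .data$category, .drop = FALSE) |>
    tidyr::unite("key", "sex", "category") |>
    tidyr::pivot_wider(names_from = "key", values_from = "n")
  manifest <- c(list(seed = seed, config_hash = config_hash,
                     package_version =
                       as.character(utils::packageVersion("phvalid"))),
                as.list(counts),
                as.list(bundle$log))
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  files <- c(files, mf)
  writeLines(c(paste("run completed:", format(Sys.time(), usetz = TRUE)),
               paste("seed:", seed)),
             file.path(outdir, "run_log.txt"))
  invisible(files)
}
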