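# CSV and config readers/writers for the pipeline's input dialects.
# Headers are validated strictly so a mis-shaped file fails at the door.

check_headers <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s file '%s' lacks column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read an age-banded death table
#'
#' Columns: `midpoint_age`, `sex`, `deaths`, optionally
#' `death_probability`, `ex`, `yll_thousands`.
#'
#' @param path CSV path.
#' @return A [death_band_table()].
#' @export
read_death_bands <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, c("midpoint_age", "sex", "deaths"), "death table", path)
  death_band_table(df)
}

#' Write an age-banded death table
#'
#' Round-trips losslessly through [read_death_bands()].
#'
#' @param table A [death_band_table()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_death_bands <- function(table, path) {
  stopifnot(inherits(table, "death_band_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read life tables from CSV
#'
#' Accepts either full tables (columns `age`, `sex`, `qx`, optional
#' `race`) at one-year age resolution, or anchor tables (columns `age`,
#' `sex`, `ex`, optional `race`) which are expanded through
#' [life_table_from_anchors()].
#'
#' @param path CSV path.
#' @param ... Passed to [life_table_from_anchors()] for anchor input.
#' @return Named list of [life_table()]s keyed `"sex"` or `"sex:race"`
#'   (`race == "All"` maps to the bare sex key).
#' @export
read_life_table <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, c("age", "sex"), "life table", path)
  if (!any(c("qx", "ex") %in% names(df))) {
    stop(sprintf("life table file '%s' needs a `qx` or `ex` column", path),
         call. = FALSE)
  }
  if (!"race" %in% names(df)) df$race <- "All"
  out <- list()
  for (s in unique(df$sex)) {
    for (r in unique(df$race[df$sex == s])) {
      part <- df[df$sex == s & df$race == r, ]
      part <- part[order(part$age), ]
      lt <- if ("qx" %in% names(df)) {
        life_table(part$age, part$qx, sex = s, race = r)
      } else {
        life_table_from_anchors(part[, c("age", "ex")], sex = s, race = r,
                                ...)
      }
      key <- if (r == "All") s else paste0(s, ":", r)
      out[[key]] <- lt
    }
  }
  out
}

#' Read expectancy anchors from CSV
#'
#' Columns: `age`, `sex`, `ex`.
#'
#' @param path CSV path.
#' @return Named list of per-sex anchor data frames.
#' @export
read_anchors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, c("age", "sex", "ex"), "anchor", path)
  lapply(split(df, df$sex), function(part) {
    part <- part[order(part$age), ]
    validate_anchors(part[, c("age", "ex")])
  })
}

#' Read a child-population table
#'
#' Columns: `state`, `sex`, `race`, `age`, `count`.
#'
#' @param path CSV path.
#' @return Validated population data frame.
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, c("state", "sex", "race", "age", "count"),
                "population", path)
  validate_population(df)
  df
}

#' Write a child-population table
#' @param pop Population data frame.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_population <- function(pop, path) {
  validate_population(pop)
  utils::write.csv(pop, path, row.names = FALSE)
  invisible(path)
}

#' Read per-state closure durations
#'
#' Columns: `state`, `closure_days`.
#'
#' @param path CSV path.
#' @return Closure data frame.
#' @export
read_closure_days <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, c("state", "closure_days"), "closure", path)
  if (any(df$closure_days < 0)) {
    stop("closure days must be non-negative", call. = FALSE)
  }
  df
}

#' Write per-state closure durations
#' @param closures Closure data frame.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_closure_days <- function(closures, path) {
  utils::write.csv(closures, path, row.names = FALSE)
  invisible(path)
}

#' Read a model configuration file
#'
#' YAML or JSON (by extension).  Recognised keys mirror the arguments of
#' [run_full_model()]: `n_draws`, `seed`, `ci_level`, `discount_rates`,
#' `horizon`, `paired`, and distribution triples `undercount` and
#' `mortality_ratio` given as lists with `minimum`, `mode`, `maximum`
#' (optional `shape`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of arguments suitable for
#'   `do.call(run_full_model, ...)`.
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be .yaml, .yml or .json", call. = FALSE))
  for (key in c("undercount", "mortality_ratio")) {
    if (!is.null(cfg[[key]])) {
      triple <- cfg[[key]]
      cfg[[key]] <- pert_params(triple$minimum, triple$mode, triple$maximum,
                                shape = if (is.null(triple$shape)) 4
                                        else triple$shape)
    }
  }
  allowed <- c("n_draws", "seed", "ci_level", "discount_rates", "horizon",
               "paired", "undercount", "mortality_ratio")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}
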