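## CSV/JSON interchange for all parameter tables and simulation outputs.
## Writers emit a canonical formatting so that read -> write round-trips
## are byte-identical on files the writers produced.

.write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- vapply(df[[j]], function(v) {
    if (is.na(v)) "" else format(v, digits = 15, trim = TRUE,
                                 scientific = FALSE)
  }, character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read / write a baseline hazard table
#'
#' `hazards.csv` schema: columns `cause`, `sex`, `age_lo`, `age_hi`,
#' `rate_per_py`; UTF-8 with a header row. Validation errors name the
#' offending rows.
#'
#' @param path File path.
#' @param max_age Age cap; defaults to the largest `age_hi` in the file.
#' @return [read_hazard_table()]: a validated [hazard_table()].
#' @export
read_hazard_table <- function(path, max_age = NULL) {
  df <- .read_csv(path)
  if (is.null(max_age)) max_age <- max(df$age_hi)
  hazard_table(df, max_age = max_age)
}

#' @rdname read_hazard_table
#' @param h A [hazard_table()] to write.
#' @export
write_hazard_table <- function(h, path) .write_csv(as.data.frame(h), path)

#' Read / write a relative-risk table
#'
#' `rr.csv` schema: columns `cause`, `sex`, `state`
#' (`never|current|former_0_4|former_5_9|former_10_19|former_20plus`),
#' `rr`.
#'
#' @param path File path.
#' @return A validated [rr_table()].
#' @export
read_rr_table <- function(path) rr_table(.read_csv(path))

#' @rdname read_rr_table
#' @param rr An [rr_table()] to write.
#' @export
write_rr_table <- function(rr, path) .write_csv(as.data.frame(rr), path)

#' Read / write smoking rates
#'
#' Single tidy schema: columns `sex`, `parameter`, `age_lo`, `age_hi`,
#' `value`, where `parameter` is `cumulative_initiation`,
#' `initiation_start_age`, `initiation_end_age` (age columns empty) or
#' `cessation_hazard_per_y` (age columns give the half-open band).
#'
#' @param path File path.
#' @return A [smoking_rates()] object.
#' @export
read_smoking_rates <- function(path) {
  df <- .read_csv(path)
  need <- c("sex", "parameter", "age_lo", "age_hi", "value")
  if (!all(need %in% names(df)))
    stop("smoking rates file needs columns: ", paste(need, collapse = ", "))
  gp <- function(p, s) {
    v <- df$value[df$parameter == p & df$sex == s]
    if (length(v) != 1L) stop("expected one '", p, "' row for sex '", s, "'")
    v
  }
  init <- vapply(sexes(), function(s) gp("cumulative_initiation", s),
                 numeric(1))
  ces <- df[df$parameter == "cessation_hazard_per_y", ]
  ces <- data.frame(sex = ces$sex, age_lo = ces$age_lo,
                    age_hi = ifelse(is.na(ces$age_hi), Inf, ces$age_hi),
                    hazard = ces$value)
  smoking_rates(initiation = init,
                start_age = gp("initiation_start_age", sexes()[1]),
                end_age = gp("initiation_end_age", sexes()[1]),
                cessation = ces)
}

#' @rdname read_smoking_rates
#' @param rates A [smoking_rates()] to write.
#' @export
write_smoking_rates <- function(rates, path) {
  rows <- do.call(rbind, lapply(sexes(), function(s) {
    r <- rates[[s]]
    rbind(data.frame(sex = s,
                     parameter = c("cumulative_initiation",
                                   "initiation_start_age",
                                   "initiation_end_age"),
                     age_lo = NA_real_, age_hi = NA_real_,
                     value = c(r$p, r$start_age, r$end_age)),
          data.frame(sex = s, parameter = "cessation_hazard_per_y",
                     age_lo = r$cessation$age_lo,
                     age_hi = ifelse(is.finite(r$cessation$age_hi),
                                     r$cessation$age_hi, NA_real_),
                     value = r$cessation$hazard))
  }))
  .write_csv(rows, path)
}

#' Read / write a standard population
#'
#' `std_population.csv` schema: `sex`, `age_lo`, `age_hi`, `weight`.
#'
#' @param path File path.
#' @return A [standard_population()].
#' @export
read_std_population <- function(path) standard_population(.read_csv(path))

#' @rdname read_std_population
#' @param std A [standard_population()] to write.
#' @export
write_std_population <- function(std, path) .write_csv(as.data.frame(std),
                                                       path)

#' Read / write scenario definitions
#'
#' `scenarios.json`: a JSON list of scenario objects as accepted by
#' [build_scenario()].
#'
#' @param path File path.
#' @return List of `scenario` objects.
#' @export
read_scenarios <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    if (!is.null(x$cumulative_initiation))
      x$cumulative_initiation <- unlist(x$cumulative_initiation)
    build_scenario(x)
  })
}

#' @rdname read_scenarios
#' @param scenarios List of `scenario` objects to write.
#' @export
write_scenarios <- function(scenarios, path) {
  out <- lapply(scenarios, function(s) {
    s <- unclass(s)
    if (!is.null(s$cumulative_initiation))
      s$cumulative_initiation <- as.list(s$cumulative_initiation)
    s[!vapply(s, is.null, logical(1))]
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Write / read a cohort result with its metadata sidecar
#'
#' The cohort is written as CSV (`id`, `sex`, `initiation_age`,
#' `quit_age`, `death_age`, `cause`) with a JSON sidecar
#' (`<path>.meta.json`) recording the scenario, seed, n and any input
#' file hashes supplied.
#'
#' @param cohort A `cohort_result`.
#' @param path CSV output path.
#' @param input_hashes Optional named character vector of md5 hashes.
#' @export
write_cohort <- function(cohort, path, input_hashes = NULL) {
  .write_csv(as.data.frame(cohort)[c("id", "sex", "initiation_age",
                                     "quit_age", "death_age", "cause")],
             path)
  meta <- list(scenario = attr(cohort, "scenario"),
               seed = attr(cohort, "seed"), n = attr(cohort, "n"),
               causes = as.character(attr(cohort, "causes")),
               residual = residual_cause(attr(cohort, "causes")),
               package_version = as.character(utils::packageVersion("smokesim")),
               input_hashes = as.list(input_hashes))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @return [read_cohort()]: the `cohort_result`.
#' @export
read_cohort <- function(path) {
  df <- .read_csv(path)
  metapath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metapath)) jsonlite::read_json(metapath) else list()
  causes <- if (!is.null(meta$causes))
    cause_list(unlist(meta$causes), meta$residual)
  else .default_causes(data.frame(cause = unique(df$cause)), NULL)
  structure(df, class = c("cohort_result", "data.frame"),
            seed = meta$seed %||% NA_integer_, n = nrow(df),
            scenario = meta$scenario %||% NA_character_, causes = causes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
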