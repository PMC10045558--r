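## Table validation and report assembly ---------------------------------------

table_schemas <- function() {
  int_ge0 <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & x == round(x)
  list(
    colony_assay = list(
      columns = c("group", "dose_gy", "cells_seeded", "dish_id", "colonies"),
      checks = list(
        dose_gy = list(fn = function(x) is.numeric(x) & !is.na(x) & x >= 0,
                       msg = "must be a non-negative number"),
        cells_seeded = list(fn = function(x) int_ge0(x) & x > 0,
                            msg = "must be a positive integer"),
        colonies = list(fn = int_ge0, msg = "must be a non-negative integer")
      ),
      row_check = list(
        fn = function(d) d$colonies <= d$cells_seeded,
        column = "colonies", msg = "exceeds cells_seeded"
      ),
      key = c("group", "dose_gy", "dish_id")
    ),
    tissue_boron = list(
      columns = c("carrier", "time_h", "tissue", "animal_id", "ug_b_per_g"),
      checks = list(
        time_h = list(fn = function(x) is.numeric(x) & !is.na(x) & x >= 0,
                      msg = "must be a non-negative number"),
        ug_b_per_g = list(fn = function(x) is.numeric(x) & !is.na(x) & x >= 0,
                          msg = "must be a non-negative concentration")
      ),
      key = c("carrier", "time_h", "tissue", "animal_id")
    ),
    cellular_uptake = list(
      columns = c("cell_line", "carrier", "phase", "time_h",
                  "ug_b_per_1e9_cells"),
      checks = list(
        phase = list(fn = function(x) x %in% c("exposure", "washout"),
                     msg = "must be 'exposure' or 'washout'"),
        time_h = list(fn = function(x) is.numeric(x) & !is.na(x) & x >= 0,
                      msg = "must be a non-negative number"),
        ug_b_per_1e9_cells = list(
          fn = function(x) is.numeric(x) & !is.na(x) & x >= 0,
          msg = "must be a non-negative concentration")
      ),
      key = NULL
    ),
    survival = list(
      columns = c("group", "animal_id", "days", "event"),
      checks = list(
        days = list(fn = function(x) is.numeric(x) & !is.na(x) & x > 0,
                    msg = "must be a positive number"),
        event = list(fn = function(x) x %in% c(0, 1),
                     msg = "must be 0 (censored) or 1 (event)")
      ),
      key = c("group", "animal_id")
    )
  )
}

#' Validate an input table against a named schema
#'
#' Parses a CSV file (or checks an in-memory data frame) against one of the
#' package's table schemas and either returns the typed table or signals a
#' `borondose_validation_error` whose `errors` field is a data frame naming,
#' per violation, the row, the column and the violated constraint.
#'
#' @param x Path to a CSV file (UTF-8, header row, "." decimal separator) or
#'   a data frame.
#' @param schema One of `"colony_assay"`, `"tissue_boron"`,
#'   `"cellular_uptake"`, `"survival"`.
#' @return The validated data frame (invisibly identical to the input data).
#' @export
#' @examples
#' tab <- gen_survival(seed = 1)
#' validate_table(tab, "survival")
validate_table <- function(x, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas))
    stop_borondose(sprintf("unknown schema '%s' (known: %s)", schema,
                           paste(names(schemas), collapse = ", ")),
                   "borondose_validation_error")
  sc <- schemas[[schema]]
  if (is.character(x)) {
    if (!file.exists(x))
      stop_borondose(sprintf("file not found: %s", x), "borondose_validation_error")
    x <- utils::read.csv(x, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.data.frame(x))
    stop_borondose("'x' must be a file path or a data frame",
                   "borondose_validation_error")
  errors <- data.frame(row = integer(), column = character(),
                       message = character(), stringsAsFactors = FALSE)
  add_err <- function(rows, column, msg) {
    if (length(rows))
      errors <<- rbind(errors, data.frame(row = rows, column = column,
                                          message = msg,
                                          stringsAsFactors = FALSE))
  }
  missing_cols <- setdiff(sc$columns, names(x))
  if (length(missing_cols)) {
    add_err(0L, missing_cols, "required column is missing")
  } else {
    for (col in names(sc$checks)) {
      ok <- sc$checks[[col]]$fn(x[[col]])
      add_err(which(!ok), col, sc$checks[[col]]$msg)
    }
    if (!is.null(sc$row_check)) {
      ok <- sc$row_check$fn(x)
      add_err(which(!ok), sc$row_check$column, sc$row_check$msg)
    }
    if (!is.null(sc$key)) {
      keyv <- do.call(paste, c(x[sc$key], sep = "\r"))
      dup <- duplicated(keyv)
      add_err(which(dup), paste(sc$key, collapse = "+"),
              "duplicated key: rows must be unique")
    }
  }
  if (nrow(errors)) {
    stop_borondose(
      sprintf("table failed '%s' validation with %d error(s); first: row %s, column %s %s",
              schema, nrow(errors), errors$row[1L], errors$column[1L],
              errors$message[1L]),
      "borondose_table_error", errors = errors
    )
  }
  x
}

## -- report assembly ----------------------------------------------------------

fmt1 <- function(x) {
  ifelse(is.na(x), "", sprintf("%.1f", round_half_up(x, 1)))
}

fmt_pm <- function(m, s) {
  ifelse(is.na(m), "",
         ifelse(is.na(s), sprintf("%.1f", round_half_up(m, 1)),
                sprintf("%.1f ± %.1f", round_half_up(m, 1),
                        round_half_up(s, 1))))
}

md_table <- function(df) {
  if (!nrow(df)) return(paste0("| ", paste(names(df), collapse = " | "), " |\n|",
                               paste(rep("---", ncol(df)), collapse = "|"), "|\n"))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(hdr, sep, body), collapse = "\n")
}

#' Assemble publication-style summary tables
#'
#' Builds display tables (one-decimal, round half up, with full-precision
#' companions) from any subset of module results.  Unknown weighting factors
#' render as blank cells, the convention for carriers whose normal-tissue
#' CBE has not been measured.  An empty bundle yields a header-only report.
#'
#' @param bundle A list with any of:
#'   \describe{
#'     \item{`tissue`}{list with `summary` ([summarize_tissue()]) and
#'       optionally `ratios` ([tissue_ratios()]).}
#'     \item{`survival`}{a [survival_summary()] data frame.}
#'     \item{`doses`}{data frame with columns `group`, `physical_gy`,
#'       `photon_eq_gy_eq` (NA = unknown factor, rendered blank).}
#'   }
#' @return List of class `borondose_report` with elements `tables` (named
#'   list of display data frames), `full` (full-precision companions) and
#'   `markdown` (single character string).
#' @export
build_report <- function(bundle = list()) {
  tables <- list()
  full <- list()
  md <- c("# borondose analysis report", "")
  if (!is.null(bundle$tissue)) {
    s <- bundle$tissue$summary
    disp <- data.frame(
      carrier = s$carrier, time_h = s$time_h, tissue = s$tissue, n = s$n,
      boron_ug_b_per_g = fmt_pm(s$mean, s$sd), stringsAsFactors = FALSE
    )
    if (!is.null(bundle$tissue$ratios)) {
      r <- bundle$tissue$ratios
      rdisp <- data.frame(carrier = r$carrier, time_h = r$time_h,
                          t_br = fmt1(r$t_br), t_bl = fmt1(r$t_bl),
                          stringsAsFactors = FALSE)
      tables$tissue_ratios <- rdisp
      full$tissue_ratios <- r
      md <- c(md, "## Tumor-to-tissue ratios", "", md_table(rdisp), "")
    }
    tables$tissue_summary <- disp
    full$tissue_summary <- s
    md <- c(md, "## Boron biodistribution", "", md_table(disp), "")
  }
  if (!is.null(bundle$survival)) {
    s <- bundle$survival
    disp <- data.frame(
      group = s$group, n = s$n,
      mean_sd_days = fmt_pm(s$mean, s$sd),
      median_days = fmt1(s$median),
      ci95 = ifelse(is.na(s$ci_low), "",
                    paste0(fmt1(s$ci_low), "-",
                           ifelse(is.na(s$ci_high), "", fmt1(s$ci_high)))),
      pct_ils = fmt1(s$pct_ils),
      p_logrank = ifelse(is.na(s$p_logrank), "",
                         signif(s$p_logrank, 2)),
      stringsAsFactors = FALSE
    )
    tables$survival <- disp
    full$survival <- s
    md <- c(md, "## Survival", "", md_table(disp), "")
  }
  if (!is.null(bundle$doses)) {
    d <- bundle$doses
    disp <- data.frame(group = d$group,
                       physical_gy = fmt1(d$physical_gy),
                       photon_eq_gy_eq = fmt1(d$photon_eq_gy_eq),
                       stringsAsFactors = FALSE)
    tables$doses <- disp
    full$doses <- d
    md <- c(md, "## Physical and photon-equivalent doses", "", md_table(disp), "")
  }
  structure(list(tables = tables, full = full,
                 markdown = paste(md, collapse = "\n")),
            class = "borondose_report")
}

#' @export
print.borondose_report <- function(x, ...) {
  cat(x$markdown, "\n")
  invisible(x)
}

#' Write a report to disk
#'
#' One CSV per display table plus a combined markdown file.
#'
#' @param report A [build_report()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "borondose_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(report$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report$tables[[nm]], p, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  mdp <- file.path(dir, "report.md")
  writeLines(report$markdown, mdp, useBytes = TRUE)
  invisible(c(paths, mdp))
}
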