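## Boron biodistribution summaries --------------------------------------------
##
## Tissue tables carry one boron concentration (ug B/g) per animal per
## (carrier, time, tissue) cell; cellular tables carry ug B/1e9 cells per
## (cell line, carrier, phase, time).  Summaries reproduce the conventions of
## published biodistribution tables: mean +/- sample SD per cell,
## ratio-of-means for tumor/brain and tumor/blood, and washout retention
## relative to the end-of-exposure concentration.

#' Summarize a tissue boron table
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' replicate animals in every (carrier, time, tissue) cell.  Cells with a
#' single animal report `NA` for the SD (absent, not zero).
#'
#' @param table Data frame with columns `carrier`, `time_h`, `tissue`,
#'   `animal_id`, `ug_b_per_g`.
#' @return Data frame with columns `carrier`, `time_h`, `tissue`, `n`,
#'   `mean`, `sd`.
#' @export
summarize_tissue <- function(table) {
  req <- c("carrier", "time_h", "tissue", "animal_id", "ug_b_per_g")
  if (!all(req %in% names(table)))
    stop_borondose(paste("tissue table needs columns:", paste(req, collapse = ", ")),
                   "borondose_validation_error")
  check_numeric_vec(table$ug_b_per_g, "ug_b_per_g", min = 0)
  key <- interaction(table$carrier, table$time_h, table$tissue, drop = TRUE)
  parts <- split(table, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(
      carrier = d$carrier[1L], time_h = d$time_h[1L], tissue = d$tissue[1L],
      n = nrow(d),
      mean = mean(d$ug_b_per_g),
      sd = if (nrow(d) > 1L) stats::sd(d$ug_b_per_g) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$carrier, out$time_h, out$tissue), , drop = FALSE]
}

#' Tumor-to-brain and tumor-to-blood ratios
#'
#' Ratio of cell means (not mean of per-animal ratios), the convention of
#' published biodistribution tables.  Both the full-precision ratio and the
#' one-decimal display value (round half up) are returned; a zero denominator
#' yields `NA` with `undefined = TRUE`.
#'
#' @param summary Output of [summarize_tissue()] containing `tumor`, `brain`
#'   and `blood` rows (tissue labels matched case-insensitively).
#' @return Data frame with columns `carrier`, `time_h`, `t_br`, `t_bl`,
#'   `t_br_display`, `t_bl_display`, `undefined`.
#' @export
tissue_ratios <- function(summary) {
  req <- c("carrier", "time_h", "tissue", "mean")
  if (!all(req %in% names(summary)))
    stop_borondose("expected a summarize_tissue() result", "borondose_validation_error")
  tis <- tolower(summary$tissue)
  key <- interaction(summary$carrier, summary$time_h, drop = TRUE)
  parts <- split(summary, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    m <- function(t) {
      i <- tolower(d$tissue) == t
      if (!any(i)) NA_real_ else d$mean[which(i)[1L]]
    }
    tu <- m("tumor"); br <- m("brain"); bl <- m("blood")
    if (is.na(tu))
      stop_borondose(sprintf("no tumor mean for carrier '%s' at %g h",
                             d$carrier[1L], d$time_h[1L]),
                     "borondose_validation_error")
    ratio <- function(den) {
      if (is.na(den)) return(NA_real_)
      if (den == 0) return(NA_real_)
      tu / den
    }
    t_br <- ratio(br); t_bl <- ratio(bl)
    data.frame(
      carrier = d$carrier[1L], time_h = d$time_h[1L],
      t_br = t_br, t_bl = t_bl,
      t_br_display = round_half_up(t_br, 1),
      t_bl_display = round_half_up(t_bl, 1),
      undefined = (!is.na(br) && br == 0) || (!is.na(bl) && bl == 0),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$carrier, out$time_h), , drop = FALSE]
}

#' Washout retention rate
#'
#' Percentage of cellular boron remaining after a washout interval relative
#' to the end-of-exposure (24 h) concentration of the same (cell line,
#' carrier):
#' `100 * concentration(24 h exposure + washout) / concentration(24 h exposure)`.
#' A washout time of 0 is the baseline itself and returns 100 by definition.
#'
#' @param uptake Data frame with columns `cell_line`, `carrier`, `phase`
#'   (`"exposure"`/`"washout"`), `time_h`, `ug_b_per_1e9_cells`.
#' @param washout_time_h Washout interval in hours.
#' @param exposure_time_h Exposure duration defining the baseline (default 24).
#' @return Data frame with columns `cell_line`, `carrier`, `retention_pct`.
#' @export
retention_rate <- function(uptake, washout_time_h, exposure_time_h = 24) {
  req <- c("cell_line", "carrier", "phase", "time_h", "ug_b_per_1e9_cells")
  if (!all(req %in% names(uptake)))
    stop_borondose(paste("uptake table needs columns:", paste(req, collapse = ", ")),
                   "borondose_validation_error")
  check_number(washout_time_h, "washout_time_h", min = 0)
  key <- interaction(uptake$cell_line, uptake$carrier, drop = TRUE)
  parts <- split(uptake, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    base_i <- d$phase == "exposure" & d$time_h == exposure_time_h
    if (!any(base_i))
      stop_borondose(sprintf("no %g h exposure baseline for %s / %s",
                             exposure_time_h, d$cell_line[1L], d$carrier[1L]),
                     "borondose_validation_error")
    baseline <- mean(d$ug_b_per_1e9_cells[base_i])
    ret <- if (baseline <= 0) {
      NA_real_
    } else if (washout_time_h == 0) {
      100
    } else {
      w_i <- d$phase == "washout" & d$time_h == washout_time_h
      if (!any(w_i))
        stop_borondose(sprintf("no %g h washout measurement for %s / %s",
                               washout_time_h, d$cell_line[1L], d$carrier[1L]),
                       "borondose_validation_error")
      100 * mean(d$ug_b_per_1e9_cells[w_i]) / baseline
    }
    data.frame(cell_line = d$cell_line[1L], carrier = d$carrier[1L],
               retention_pct = ret, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$cell_line, out$carrier), , drop = FALSE]
}

#' Two-sample comparison of boron uptake
#'
#' Student's two-sample t-test (pooled variance by default, matching the
#' convention for cellular uptake comparisons; Welch available via
#' `var_equal = FALSE`).
#'
#' @param x,y Numeric vectors of concentrations (n >= 2 each).
#' @param var_equal Pooled-variance Student's t (default `TRUE`).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return List with `statistic`, `df`, `p_value`, `significant`, `method`.
#' @export
compare_uptake <- function(x, y, var_equal = TRUE, alpha = 0.05) {
  check_numeric_vec(x, "x"); check_numeric_vec(y, "y")
  if (length(x) < 2L || length(y) < 2L)
    stop_borondose("need at least 2 observations per group",
                   "borondose_insufficient_data_error")
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, significant = ht$p.value < alpha,
       method = ht$method)
}
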