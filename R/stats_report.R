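## Group summaries, the study's planned pairwise Student t-tests, derived
## swelling-reduction percentages, and Table-shaped report assembly.

validate_group_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("group", "value")
  if (!all(need %in% names(table)))
    stop("group table needs columns 'group' and 'value'", call. = FALSE)
  invisible(table)
}

#' Per-group mean, SD and n
#'
#' Sample SD uses the n - 1 denominator. Errors on singleton groups.
#'
#' @param table data frame with columns `group`, `value` (and optionally
#'   `measure`, summarised separately)
#' @return data frame with columns `group` (and `measure`), `mean`, `sd`, `n`
#' @export
group_summary <- function(table) {
  validate_group_table(table)
  by <- if ("measure" %in% names(table))
    list(group = table$group, measure = table$measure)
  else list(group = table$group)
  agg <- aggregate(table$value, by = by,
                   FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                       n = length(v)))
  out <- cbind(agg[setdiff(names(agg), "x")], as.data.frame(agg$x))
  if (any(out$n < 2))
    stop("singleton group: ", paste(out$group[out$n < 2], collapse = ", "),
         call. = FALSE)
  out
}

#' The study's planned comparison scheme
#'
#' Two families of pairwise tests: each enzyme-treated group against the
#' untreated control, and each crosslinked group against the non-crosslinked
#' group with the same enzyme treatment.
#'
#' @return data frame with columns `group_a`, `group_b` (b is the reference)
#' @export
default_comparison_plan <- function() {
  fam <- c("Control", "COLG", "ChaseABC")
  enzyme_vs_control <- data.frame(group_a = c("COLG", "ChaseABC"),
                                  group_b = "Control")
  cxl_vs_base <- do.call(rbind, lapply(fam, function(f)
    data.frame(group_a = c(paste0(f, "-CXL"), paste0(f, "-CXL+Col")),
               group_b = f)))
  rbind(enzyme_vs_control, cxl_vs_base)
}

#' Planned pairwise two-sample t-tests
#'
#' Two-sided Student t-tests (pooled variance, the study's stated test) per
#' planned pair; Welch's correction is available as a flag. Significance is
#' declared at `alpha` with no multiple-testing correction, reproducing the
#' study's reporting convention.
#'
#' @param table data frame with columns `group`, `value`
#' @param plan data frame of pairs (`group_a`, `group_b`); defaults to
#'   [default_comparison_plan()] restricted to groups present
#' @param welch use Welch's unequal-variance t-test instead of pooled
#' @param alpha significance level
#' @return data frame: `group_a`, `group_b`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `t_statistic`, `p_value`, `significant`
#' @export
pairwise_ttests <- function(table, plan = NULL, welch = FALSE, alpha = 0.05) {
  validate_group_table(table)
  if (is.null(plan)) {
    plan <- default_comparison_plan()
    plan <- plan[plan$group_a %in% table$group &
                 plan$group_b %in% table$group, , drop = FALSE]
  } else {
    missing <- setdiff(unique(c(plan$group_a, plan$group_b)), table$group)
    if (length(missing))
      stop("groups missing from the table: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    a <- table$value[table$group == plan$group_a[i]]
    b <- table$value[table$group == plan$group_b[i]]
    if (length(a) < 2L || length(b) < 2L)
      stop("both groups need n >= 2", call. = FALSE)
    tt <- stats::t.test(a, b, var.equal = !welch)
    data.frame(group_a = plan$group_a[i], group_b = plan$group_b[i],
               mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               significant = tt$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' Relative swelling reduction between two groups, in percent
#'
#' `100 * (mean_b - mean_a) / mean_b`, where `group_b` is the reference
#' (conventional CXL) and `group_a` the comparison (CXL with soluble
#' collagen). Accepts either a per-eye value table (`group`, `value`) or a
#' summary table (`group`, `mean`).
#'
#' @param table data frame; per-eye values or group summary
#' @param group_a comparison group label
#' @param group_b reference group label
#' @return percent reduction (positive when `group_a` swells less)
#' @export
percent_swelling_reduction <- function(table, group_a, group_b) {
  stopifnot(is.data.frame(table))
  get_mean <- function(g) {
    if ("mean" %in% names(table)) {
      m <- table$mean[table$group == g]
    } else {
      validate_group_table(table)
      m <- mean(table$value[table$group == g])
    }
    if (!length(m) || is.na(m[1]))
      stop("group not found: ", g, call. = FALSE)
    m[1]
  }
  ma <- get_mean(group_a); mb <- get_mean(group_b)
  if (mb == 0) stop("reference group mean is zero", call. = FALSE)
  100 * (mb - ma) / mb
}

flag_for_reference <- function(ref) {
  c(Control = "*", COLG = "#", ChaseABC = "^")[ref]
}

#' Assemble Table-shaped summary reports with significance flags
#'
#' One data frame per measure with `mean +/- SD` formatting and footnote
#' flags following the study's convention: `*` significant vs Control, `#`
#' vs COLG, `^` vs ChaseABC. Accepts a per-eye long table (`group`, `value`,
#' `measure`), in which case planned t-tests supply the flags, or a
#' pre-summarised table (`group`, `measure`, `mean`, `sd`), in which case
#' flags are omitted. Measures with no rows are dropped. Output is a pure
#' function of the input, so report generation is idempotent.
#'
#' @param table long per-eye table or summary table
#' @param plan comparison plan for the flags; see [pairwise_ttests()]
#' @param digits decimal places for the formatted `mean_sd` column
#' @return named list of data frames, one per measure
#' @export
build_report <- function(table, plan = NULL, digits = 2) {
  stopifnot(is.data.frame(table))
  if (!"measure" %in% names(table)) table$measure <- "value"
  measures <- unique(table$measure)
  out <- list()
  for (m in measures) {
    sub <- table[table$measure == m, , drop = FALSE]
    if (!nrow(sub)) next
    if ("value" %in% names(sub)) {
      s <- group_summary(sub[c("group", "value")])
      tests <- pairwise_ttests(sub[c("group", "value")], plan = plan)
      flags <- vapply(s$group, function(g) {
        hits <- tests$significant & tests$group_a == g
        paste(flag_for_reference(tests$group_b[hits]), collapse = "")
      }, character(1))
      s$flag <- unname(flags)
    } else {
      stopifnot(all(c("mean", "sd") %in% names(sub)))
      s <- sub[c("group", "mean", "sd")]
    }
    s$mean_sd <- sprintf(paste0("%.", digits, "f±%.", digits, "f"),
                         s$mean, s$sd)
    rownames(s) <- NULL
    out[[m]] <- s
  }
  out
}

#' Write a report to per-measure CSV files
#'
#' @param report a [build_report()] result
#' @param dir output directory (created if needed)
#' @return character vector of file paths, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(report), function(m) {
    p <- file.path(dir, paste0("summary_", m, ".csv"))
    utils::write.csv(report[[m]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
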