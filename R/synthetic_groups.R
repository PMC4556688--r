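#' Canonical nine-group design labels
#'
#' Three enzyme families (Control, COLG = collagenase type II, ChaseABC =
#' chondroitinase ABC), each untreated, UVA-crosslinked (CXL) or crosslinked
#' with soluble collagen (CXL+Col).
#'
#' @return character vector of the nine group labels
#' @export
study_groups <- function() {
  fam <- c("Control", "COLG", "ChaseABC")
  as.vector(vapply(fam, function(f) c(f, paste0(f, "-CXL"),
                                      paste0(f, "-CXL+Col")),
                   character(3)))
}

#' Generate a per-eye group measurement table
#'
#' Values are drawn normal(mean, sd) per group, emulating per-eye central
#' corneal thickness (or any other per-sample measure).
#'
#' @param group_specs data frame with columns `group`, `mean`, `sd`, `n`
#' @param measure measure label stored in the table
#' @param seed integer seed
#' @return data frame with columns `group`, `eye_id`, `value`, `measure`
#' @export
generate_group_table <- function(group_specs, measure = "cct_um", seed = 1L) {
  stopifnot(is.data.frame(group_specs),
            all(c("group", "mean", "sd", "n") %in% names(group_specs)))
  if (any(group_specs$sd < 0)) stop("sd must be nonnegative", call. = FALSE)
  if (any(group_specs$n < 2)) stop("each group needs n >= 2", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(group_specs)), function(i) {
      s <- group_specs[i, ]
      data.frame(group = s$group,
                 eye_id = sprintf("%s-%02d", s$group, seq_len(s$n)),
                 value = stats::rnorm(s$n, s$mean, s$sd),
                 measure = measure)
    })
    do.call(rbind, rows)
  })
}

#' Packaged reference summary tables
#'
#' Loads the bundled mean +/- SD summary tables for central corneal thickness
#' (`"cct"`), TEM morphometry (`"morphometry"`: fibril diameter, nearest
#' -neighbour spacing, per-window spot density) or DSC transition temperature
#' (`"transition"`), for the nine-group design.
#'
#' @param which one of `"cct"`, `"morphometry"`, `"transition"`
#' @return data frame with columns `group`, `measure`, `mean`, `sd`
#' @export
load_reference_table <- function(which = c("cct", "morphometry",
                                           "transition")) {
  which <- match.arg(which)
  file <- c(cct = "table_cct.csv", morphometry = "table_morphometry.csv",
            transition = "table_transition.csv")[[which]]
  path <- system.file("extdata", file, package = "fibrilquant")
  if (path == "") stop("bundled table not found: ", file, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
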