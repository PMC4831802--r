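#' Construct a gonad sample
#'
#' One mitotic zone's per-cell measurements plus experiment metadata. Cells
#' are rows of `(cell_id, dna_content, edu, ph3)` where `dna_content` is
#' relative DNA content (arbitrary units until normalized to the 1n--2n
#' axis), `edu` marks EdU incorporation and `ph3` marks phospho-histone H3
#' (M-phase) staining, both as 0/1.
#'
#' @param worm_id Worm identifier (string).
#' @param arm Gonadal arm, `"L"` or `"R"`.
#' @param condition Condition label (genotype/treatment).
#' @param assay `"pulse_chase"` or `"continuous"`.
#' @param pulse_h,chase_h,label_h Pulse duration, chase time (pulse-chase)
#'   or continuous-labeling duration (continuous), in hours; unused fields
#'   are `NA`.
#' @param cells Data frame with columns `cell_id`, `dna_content`, `edu`,
#'   `ph3`. May be empty, in which case the sample is flagged `empty`.
#' @return An object of class `gonad_sample`.
#' @export
gonad_sample <- function(worm_id, arm = c("L", "R"), condition = "unknown",
                         assay = c("pulse_chase", "continuous"),
                         pulse_h = NA_real_, chase_h = NA_real_,
                         label_h = NA_real_, cells) {
  arm <- match.arg(arm)
  assay <- match.arg(assay)
  for (nm in c("pulse_h", "chase_h", "label_h")) {
    v <- get(nm)
    if (!is.na(v) && (!is.numeric(v) || v < 0))
      stop_field(nm, "must be NA or a non-negative number of hours")
  }
  stopifnot(is.data.frame(cells))
  req <- c("cell_id", "dna_content", "edu", "ph3")
  miss <- setdiff(req, names(cells))
  if (length(miss))
    stop(sprintf("cells table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(cells) && !all(cells$edu %in% c(0, 1)))
    stop_field("edu", "must be 0/1")
  if (nrow(cells) && !all(cells$ph3 %in% c(0, 1)))
    stop_field("ph3", "must be 0/1")
  structure(list(worm_id = as.character(worm_id), arm = arm,
                 condition = as.character(condition), assay = assay,
                 pulse_h = pulse_h, chase_h = chase_h, label_h = label_h,
                 cells = cells[, req], empty = nrow(cells) == 0L),
            class = "gonad_sample")
}

#' @export
print.gonad_sample <- function(x, ...) {
  tm <- if (x$assay == "pulse_chase")
    sprintf("pulse %g h, chase %g h", x$pulse_h, x$chase_h)
  else sprintf("continuous %g h", x$label_h)
  cat(sprintf("Gonad sample %s.%s [%s, %s]: %d cells, %d EdU+, %d PH3+\n",
              x$worm_id, x$arm, x$condition, tm, nrow(x$cells),
              sum(x$cells$edu), sum(x$cells$ph3)))
  invisible(x)
}
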