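# Delimited-text formats: per-cell tables, template bundles, preset
# configuration, labeling summaries. Everything is plain inspectable text.

cell_table_columns <- c("worm_id", "arm", "condition", "assay", "pulse_h",
                        "chase_h", "label_h", "cell_id", "dna_content",
                        "edu", "ph3")

#' Write gonad samples as a per-cell table
#'
#' One row per cell with the standard schema: `worm_id`, `arm`,
#' `condition`, `assay`, `pulse_h`, `chase_h`, `label_h`, `cell_id`,
#' `dna_content`, `edu`, `ph3`. Missing numeric metadata is written as an
#' empty field.
#'
#' @param samples List of [gonad_sample()] objects.
#' @param path Output file path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cell_tables <- function(samples, path, sep = ",") {
  stopifnot(is.list(samples), length(samples) > 0L)
  rows <- lapply(samples, function(g) {
    stopifnot(inherits(g, "gonad_sample"))
    if (!nrow(g$cells)) return(NULL)
    data.frame(worm_id = g$worm_id, arm = g$arm, condition = g$condition,
               assay = g$assay, pulse_h = g$pulse_h, chase_h = g$chase_h,
               label_h = g$label_h, g$cells, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df[, cell_table_columns], path, sep = sep, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# G1-peak calibration: map the mode of the lower half of the content
# distribution to 1.0 (so twice that is 2.0), then clamp onto [1, 2]. The
# estimate is scale-equivariant, so downstream results do not depend on
# the raw intensity units.
g1_peak_normalize <- function(x) {
  lower <- x[x <= stats::median(x)]
  peak <- if (length(lower) >= 5L) {
    d <- stats::density(lower)
    d$x[which.max(d$y)]
  } else {
    stats::median(lower)
  }
  if (!is.finite(peak) || peak <= 0)
    stop("G1-peak normalization failed: non-positive peak estimate",
         call. = FALSE)
  pmin(2, pmax(1, x / peak))
}

#' Read a per-cell table into gonad samples
#'
#' Delimiter (comma or tab) is auto-detected from the header. Rows are
#' grouped by `(worm_id, arm)` into [gonad_sample()] objects. Raw DNA
#' content in arbitrary units is rescaled per gonad onto the 1n--2n axis by
#' G1-peak normalization (`normalize = "g1peak"`, the default); data
#' already on \[1, 2\] can be read back verbatim with `normalize = "none"`.
#'
#' @param path Input file path.
#' @param normalize `"g1peak"` or `"none"`.
#' @return List of [gonad_sample()] objects.
#' @export
read_cell_tables <- function(path, normalize = c("g1peak", "none")) {
  normalize <- match.arg(normalize)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  missing_cols <- setdiff(cell_table_columns, names(df))
  if (length(missing_cols))
    stop(sprintf("cell table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), cell_table_columns)
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    df <- df[, cell_table_columns]
  }
  for (col in c("edu", "ph3")) {
    bad <- which(!df[[col]] %in% c(0L, 1L))
    if (length(bad))
      stop(sprintf("non-binary `%s` value at data line %d", col, bad[1L]),
           call. = FALSE)
  }
  key <- paste(df$worm_id, df$arm, sep = ".")
  lapply(split(df, factor(key, levels = unique(key))), function(gd) {
    content <- gd$dna_content
    if (normalize == "g1peak") content <- g1_peak_normalize(content)
    gonad_sample(worm_id = gd$worm_id[1L], arm = gd$arm[1L],
                 condition = gd$condition[1L], assay = gd$assay[1L],
                 pulse_h = gd$pulse_h[1L], chase_h = gd$chase_h[1L],
                 label_h = gd$label_h[1L],
                 cells = data.frame(cell_id = gd$cell_id,
                                    dna_content = content,
                                    edu = gd$edu, ph3 = gd$ph3,
                                    stringsAsFactors = FALSE))
  })
}

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

#' Write a template library bundle
#'
#' Plain delimited text: `#key=value` metadata header lines followed by a
#' CSV body with columns `phase_index`, `bin`, `count_pos`, `count_neg`.
#'
#' @param lib A [build_template_library()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_template_library <- function(lib, path) {
  stopifnot(inherits(lib, "template_library"))
  cp <- lib$params
  meta <- c(k = lib$k, pulse_duration = fmt_num(lib$pulse_duration),
            n_sim = lib$n_sim, noise_cv = fmt_num(lib$noise_cv),
            f_g1 = fmt_num(cp$f_g1), f_s = fmt_num(cp$f_s),
            f_g2 = fmt_num(cp$f_g2), f_m = fmt_num(cp$f_m),
            t_c = fmt_num(cp$t_c),
            bin_edges = paste(fmt_num(lib$bin_edges), collapse = ";"))
  body <- do.call(rbind, lapply(seq_len(lib$k), function(j) {
    tm <- lib$templates[[j]]
    data.frame(phase_index = j - 1L,
               bin = seq_along(tm$counts_pos),
               count_pos = tm$counts_pos, count_neg = tm$counts_neg)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s", names(meta), meta), con)
  utils::write.table(body, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a template library bundle
#'
#' @param path A file written by [write_template_library()].
#' @return A `template_library` object.
#' @export
read_template_library <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  body <- utils::read.table(text = lines[!grepl("^#", lines)],
                            header = TRUE, sep = ",")
  k <- as.integer(meta[["k"]])
  bin_edges <- as.numeric(strsplit(meta[["bin_edges"]], ";")[[1L]])
  params <- cycle_params(as.numeric(meta[["f_g1"]]),
                         as.numeric(meta[["f_s"]]),
                         as.numeric(meta[["f_g2"]]),
                         as.numeric(meta[["f_m"]]),
                         as.numeric(meta[["t_c"]]))
  templates <- lapply(seq_len(k) - 1L, function(j) {
    bj <- body[body$phase_index == j, ]
    bj <- bj[order(bj$bin), ]
    histogram_pair(bj$count_pos, bj$count_neg, bin_edges)
  })
  structure(list(params = params, k = k, phases = (seq_len(k) - 1L) / k,
                 templates = templates,
                 pulse_duration = as.numeric(meta[["pulse_duration"]]),
                 n_sim = as.integer(meta[["n_sim"]]),
                 bin_edges = bin_edges,
                 noise_cv = as.numeric(meta[["noise_cv"]])),
            class = "template_library")
}

#' Write a condition preset as a key=value config
#'
#' @param preset A [condition_preset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_preset <- function(preset, path) {
  stopifnot(inherits(preset, "condition_preset"))
  cp <- preset$cycle
  vals <- c(name = preset$name,
            f_g1 = fmt_num(cp$f_g1), f_s = fmt_num(cp$f_s),
            f_g2 = fmt_num(cp$f_g2), f_m = fmt_num(cp$f_m),
            t_c = fmt_num(cp$t_c),
            pi_d = fmt_num(preset$pi_d), k_da = fmt_num(preset$k_da),
            k_ad = fmt_num(preset$k_ad),
            zone_size_mean = fmt_num(preset$zone_size_mean),
            zone_size_sd = fmt_num(preset$zone_size_sd),
            noise_cv = fmt_num(preset$noise_cv),
            edu_fn = fmt_num(preset$edu_fn),
            edu_fp = fmt_num(preset$edu_fp),
            ph3_miss = fmt_num(preset$ph3_miss),
            pulse_h = fmt_num(preset$pulse_h))
  writeLines(sprintf("%s=%s", names(vals), vals), path)
  invisible(path)
}

#' Read a condition preset config
#'
#' @param path A file written by [write_preset()].
#' @return A [condition_preset()].
#' @export
read_preset <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  num <- function(nm) as.numeric(vals[[nm]])
  condition_preset(vals[["name"]],
                   cycle_params(num("f_g1"), num("f_s"), num("f_g2"),
                                num("f_m"), num("t_c")),
                   pi_d = num("pi_d"), k_da = num("k_da"),
                   k_ad = num("k_ad"),
                   zone_size_mean = num("zone_size_mean"),
                   zone_size_sd = num("zone_size_sd"),
                   noise_cv = num("noise_cv"), edu_fn = num("edu_fn"),
                   edu_fp = num("edu_fp"), ph3_miss = num("ph3_miss"),
                   pulse_h = num("pulse_h"))
}

#' Write / read a continuous-labeling summary
#'
#' CSV with columns `worm_id`, `arm`, `condition`, `label_h`, `labeled`.
#'
#' @param summary Data frame with the columns above.
#' @param path File path.
#' @return `path` (write) or the validated data frame (read).
#' @export
write_labeling_summary <- function(summary, path) {
  req <- c("worm_id", "arm", "condition", "label_h", "labeled")
  stopifnot(all(req %in% names(summary)))
  utils::write.csv(summary[, req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labeling_summary
#' @export
read_labeling_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("worm_id", "arm", "condition", "label_h", "labeled")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("labeling summary missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!all(df$labeled %in% c(0L, 1L)))
    stop("`labeled` must be 0/1", call. = FALSE)
  df
}
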